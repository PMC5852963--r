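# Nei-Gojobori (1986) pathway-counting dN/dS with Jukes-Cantor correction.

# Standard genetic code, codon -> one-letter amino acid ("*" = stop).
GENETIC_CODE_DG <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

SENSE_CODONS <- names(GENETIC_CODE_DG)[GENETIC_CODE_DG != "*"]
BASES <- c("A", "C", "G", "T")

.dnds_cache <- new.env(parent = emptyenv())

split_codons <- function(seq, name = "sequence") {
  seq <- toupper(gsub("\\s", "", seq))
  if (nchar(seq) %% 3 != 0) {
    stop_dg(sprintf("%s length is not a multiple of 3.", name),
            "dualgene_seq_error")
  }
  if (grepl("[^ACGT]", seq)) {
    stop_dg(sprintf("%s contains non-ACGT symbols.", name),
            "dualgene_seq_error")
  }
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  if (any(GENETIC_CODE_DG[codons] == "*")) {
    stop_dg(sprintf("%s contains an internal stop codon.", name),
            "dualgene_seq_error")
  }
  codons
}

# Synonymous site count of one codon: at each position, the fraction of the
# three alternative bases giving a synonymous change. Changes to stop codons
# count as nonsynonymous, so syn + nonsyn sites = 3 per codon.
codon_syn_sites <- function(codon) {
  key <- paste0("S_", codon)
  if (!is.null(.dnds_cache[[key]])) return(.dnds_cache[[key]])
  aa <- GENETIC_CODE_DG[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (GENETIC_CODE_DG[[alt]] == aa) s <- s + 1 / 3
    }
  }
  .dnds_cache[[key]] <- s
  s
}

# Synonymous/nonsynonymous differences between two codons, averaged with
# equal weight over all mutational pathways. Pathways passing through a stop
# codon are excluded when at least one stop-free pathway exists.
codon_pair_diffs <- function(c1, c2) {
  key <- paste0("D_", c1, c2)
  if (!is.null(.dnds_cache[[key]])) return(.dnds_cache[[key]])
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0L) {
    out <- c(sd = 0, nd = 0)
  } else {
    orders <- combinat_perms(length(pos))
    paths <- lapply(orders, function(ord) {
      cur <- c1
      sd <- 0; nd <- 0; blocked <- FALSE
      for (k in pos[ord]) {
        nxt <- cur
        substr(nxt, k, k) <- substr(c2, k, k)
        if (GENETIC_CODE_DG[[nxt]] == "*") blocked <- TRUE
        if (GENETIC_CODE_DG[[nxt]] == GENETIC_CODE_DG[[cur]]) {
          sd <- sd + 1
        } else {
          nd <- nd + 1
        }
        cur <- nxt
      }
      list(sd = sd, nd = nd, blocked = blocked)
    })
    ok <- !vapply(paths, `[[`, logical(1), "blocked")
    use <- if (any(ok)) paths[ok] else paths
    out <- c(sd = mean(vapply(use, `[[`, numeric(1), "sd")),
             nd = mean(vapply(use, `[[`, numeric(1), "nd")))
  }
  .dnds_cache[[key]] <- out
  out
}

# All permutations of 1:n for n <= 3.
combinat_perms <- function(n) {
  switch(n,
         list(1L),
         list(c(1L, 2L), c(2L, 1L)),
         list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
              c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
}

jukes_cantor <- function(p, what) {
  if (p >= 3 / 4) {
    stop_dg(sprintf("%s proportion %.3f at or beyond Jukes-Cantor saturation (3/4).",
                    what, p), "dualgene_saturation_error")
  }
  -3 / 4 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori dN/dS for a codon-aligned sequence pair
#'
#' Counts synonymous and nonsynonymous sites and differences by the
#' Nei-Gojobori (1986) pathway method (all mutational pathways weighted
#' equally; stop-passing pathways excluded when avoidable; changes to stop
#' codons counted as nonsynonymous so that sites sum to three per codon)
#' and applies the Jukes-Cantor correction
#' `d = -(3/4) log(1 - (4/3) p)` to both proportions.
#'
#' @param seq_a,seq_b Gap-free coding sequences of equal length (multiple
#'   of 3, ACGT only, no internal stops).
#' @return One-row tibble: `dN`, `dS`, `omega` (`NA` when `dS = 0`),
#'   `S_sites`, `N_sites`, `Sd`, `Nd`, `n_codons`.
#' @export
#' @examples
#' dnds_nei_gojobori("TTTAAA", "TTTAAA") # identical: dN = dS = 0
dnds_nei_gojobori <- function(seq_a, seq_b) {
  ca <- split_codons(seq_a, "seq_a")
  cb <- split_codons(seq_b, "seq_b")
  if (length(ca) != length(cb)) {
    stop_dg("Sequences differ in length.", "dualgene_seq_error")
  }
  S_a <- sum(vapply(ca, codon_syn_sites, numeric(1)))
  S_b <- sum(vapply(cb, codon_syn_sites, numeric(1)))
  S <- (S_a + S_b) / 2
  N <- 3 * length(ca) - S
  diffs <- mapply(function(x, y) codon_pair_diffs(x, y), ca, cb)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  dS <- if (pS > 0) jukes_cantor(pS, "Synonymous") else 0
  dN <- if (pN > 0) jukes_cantor(pN, "Nonsynonymous") else 0
  tibble(
    dN = dN, dS = dS,
    omega = if (dS > 0) dN / dS else NA_real_,
    S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
    n_codons = length(ca)
  )
}

#' Read paired coding sequences from a FASTA file
#'
#' Pairs are matched by identifier suffix: records named `<id>_a` and
#' `<id>_b` (or `<id>|a` / `<id>|b`) form one alignment pair.
#'
#' @param path FASTA file path.
#' @return Tibble (`pair_id`, `seq_a`, `seq_b`).
#' @export
read_codon_pairs <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- grepl("^>", lines)
  id <- cumsum(hdr)
  names_all <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste0, "", collapse = "")
  suffix <- sub("^.*[_|]", "", names_all)
  base <- sub("[_|][ab]$", "", names_all)
  if (!all(suffix %in% c("a", "b"))) {
    stop_dg("FASTA records must be named <id>_a / <id>_b.",
            "dualgene_format_error")
  }
  tibble(pair_id = base, suffix = suffix, seq = unname(seqs)) %>%
    tidyr::pivot_wider(names_from = "suffix", values_from = "seq",
                       names_prefix = "seq_")
}
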