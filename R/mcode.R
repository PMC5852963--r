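# MCODE-style dense-module detection, re-implemented from the published
# description of the algorithm: vertex weighting by the density of the
# highest k-core of each node's closed neighborhood, then seeded greedy
# growth with a vertex-weight-percentage cutoff.

core_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE-style vertex weights
#'
#' For each node `v`, take the subgraph induced on its closed neighborhood,
#' find the highest k-core of that subgraph, and set
#' `weight(v) = k_max * density(core)`. Nodes with degree below
#' `degree_cutoff` receive weight 0 (and are never seeds).
#'
#' @param network Simple undirected `igraph`.
#' @param degree_cutoff Minimum degree for a node to be scored; default 2.
#' @return Numeric weight vector in vertex order.
#' @export
mcode_weights <- function(network, degree_cutoff = 2) {
  n <- igraph::vcount(network)
  if (n == 0L) return(numeric(0))
  deg <- igraph::degree(network)
  adj <- igraph::adjacent_vertices(network, igraph::V(network))
  vapply(seq_len(n), function(i) {
    if (deg[[i]] < degree_cutoff) return(0)
    nb <- c(i, as.integer(adj[[i]]))
    sub <- igraph::induced_subgraph(network, nb)
    cores <- igraph::coreness(sub)
    k_max <- max(cores)
    if (k_max == 0L) return(0)
    core <- igraph::induced_subgraph(sub, which(cores >= k_max))
    k_max * core_density(core)
  }, numeric(1))
}

#' Detect dense modules (MCODE-style complexes)
#'
#' Seeds are taken in decreasing weight order (ties broken by
#' lexicographic gene id). From each unseen seed, neighbors whose weight is
#' at least `(1 - vwp) * seed_weight` are added breadth-first; nodes already
#' assigned to a complex are skipped. With `haircut`, nodes singly connected
#' within the complex are removed iteratively (leaving the complex's
#' 2-core); complexes emptied by the haircut are discarded. Complexes are
#' ranked by `score = density * size`.
#'
#' @param network Simple undirected `igraph`.
#' @param vwp Vertex weight percentage in `[0, 1)`; default 0.2.
#' @param haircut Remove singly-connected nodes; default TRUE.
#' @param fluff Add high-density neighborhoods around the complex;
#'   default FALSE.
#' @param fluff_density Neighborhood-density threshold used when
#'   `fluff = TRUE`; default 0.1.
#' @param degree_cutoff Minimum degree for scored nodes; default 2.
#' @return Object of class `dg_mcode`: a list with `complexes` (tibble
#'   `rank`, `score`, `size`, `seed`, `members` list-column) and `weights`
#'   (tibble `gene_id`, `mcode_weight`).
#' @export
mcode_complexes <- function(network, vwp = 0.2, haircut = TRUE,
                            fluff = FALSE, fluff_density = 0.1,
                            degree_cutoff = 2) {
  stopifnot(vwp >= 0, vwp < 1)
  names_v <- igraph::V(network)$name
  w <- mcode_weights(network, degree_cutoff = degree_cutoff)
  res <- list()
  if (length(w) > 0L) {
    order_idx <- order(-w, names_v)
    assigned <- rep(FALSE, length(w))
    adj <- igraph::adjacent_vertices(network, igraph::V(network))
    for (seed in order_idx) {
      if (assigned[[seed]] || w[[seed]] <= 0) next
      cutoff <- (1 - vwp) * w[[seed]]
      members <- seed
      assigned[[seed]] <- TRUE
      frontier <- seed
      while (length(frontier) > 0L) {
        nxt <- unique(unlist(lapply(frontier, function(i) as.integer(adj[[i]]))))
        nxt <- nxt[!assigned[nxt] & w[nxt] >= cutoff]
        if (length(nxt) == 0L) break
        assigned[nxt] <- TRUE
        members <- c(members, nxt)
        frontier <- nxt
      }
      if (fluff) {
        fringe <- unique(unlist(lapply(members, function(i) as.integer(adj[[i]]))))
        fringe <- setdiff(fringe, members)
        keep <- vapply(fringe, function(i) {
          nb <- c(i, as.integer(adj[[i]]))
          core_density(igraph::induced_subgraph(network, nb)) > fluff_density
        }, logical(1))
        members <- c(members, fringe[keep]) # fluffed nodes may repeat across complexes
      }
      sub <- igraph::induced_subgraph(network, members)
      if (haircut) {
        repeat {
          low <- which(igraph::degree(sub) < 2)
          if (length(low) == 0L || igraph::vcount(sub) == 0L) break
          sub <- igraph::delete_vertices(sub, low)
        }
      }
      if (igraph::vcount(sub) < 2L) next
      res[[length(res) + 1L]] <- list(
        seed = names_v[[seed]],
        members = sort(igraph::V(sub)$name),
        size = as.integer(igraph::vcount(sub)),
        score = core_density(sub) * igraph::vcount(sub)
      )
    }
  }
  complexes <- if (length(res) == 0L) {
    tibble(rank = integer(), score = numeric(), size = integer(),
           seed = character(), members = list())
  } else {
    tibble(
      score = vapply(res, `[[`, numeric(1), "score"),
      size = vapply(res, `[[`, integer(1), "size"),
      seed = vapply(res, `[[`, character(1), "seed"),
      members = lapply(res, `[[`, "members")
    ) %>%
      arrange(desc(.data$score),
              vapply(.data$members, `[[`, character(1), 1L)) %>%
      mutate(rank = row_number()) %>%
      select("rank", "score", "size", "seed", "members")
  }
  structure(
    list(complexes = complexes,
         weights = tibble(gene_id = names_v, mcode_weight = w)),
    class = "dg_mcode"
  )
}

#' @export
print.dg_mcode <- function(x, ...) {
  cat(sprintf("MCODE-style module detection: %d complex(es)\n",
              nrow(x$complexes)))
  print(x$complexes, ...)
  invisible(x)
}

#' Tidy MCODE complexes into one row per member gene
#'
#' @param x A `dg_mcode` object.
#' @param ... Unused.
#' @return Tibble (`rank`, `score`, `size`, `gene_id`).
#' @method tidy dg_mcode
#' @export
tidy.dg_mcode <- function(x, ...) {
  x$complexes %>%
    select("rank", "score", "size", "members") %>%
    tidyr::unnest_longer("members", values_to = "gene_id")
}

#' One-row summary of an MCODE result
#'
#' @param x A `dg_mcode` object.
#' @param ... Unused.
#' @return Tibble (`n_complexes`, `top_score`, `top_size`).
#' @method glance dg_mcode
#' @export
glance.dg_mcode <- function(x, ...) {
  tibble(
    n_complexes = nrow(x$complexes),
    top_score = if (nrow(x$complexes)) x$complexes$score[[1L]] else NA_real_,
    top_size = if (nrow(x$complexes)) x$complexes$size[[1L]] else NA_integer_
  )
}
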