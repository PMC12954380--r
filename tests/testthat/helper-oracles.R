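# Independent oracles used to check the package's fast implementations.
# These deliberately use different algorithms (exhaustive enumeration,
# brute-force scans, QR-based linear fits) from the code paths they verify.

# Exhaustive grid search for the Nernstian midpoint: scan Em on a fixed
# step, fitting the conditionally linear (a, c) by QR (stats::lm.fit) at
# every grid point, and return the grid minimizer.
oracle_grid_em <- function(E, y, config = processing_config(),
                           step = 0.1, pad = 100) {
  w <- 1000 * config$gas_constant * config$temperature /
    (config$electrons_z * config$faraday)
  grid <- seq(min(E) - pad, max(E) + pad, by = step)
  best_em <- NA_real_
  best_rss <- Inf
  for (m in grid) {
    g <- 1 / (exp((E - m) / w) + 1)
    fit <- stats::lm.fit(cbind(g, 1), y)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      best_em <- m
    }
  }
  best_em
}

# Brute-force minimum interatomic distance: explicit double loop.
oracle_min_dist <- function(a, b) {
  pa <- a$atoms[, c("x", "y", "z")]
  pb <- b$atoms[, c("x", "y", "z")]
  best <- Inf
  for (i in seq_len(nrow(pa)))
    for (j in seq_len(nrow(pb)))
      best <- min(best, sqrt(sum((as.numeric(pa[i, ]) -
                                    as.numeric(pb[j, ]))^2)))
  best
}

# Enumerate every simple path between two nodes of a transfer graph and
# return the optimum under (bottleneck, then steps, then lexicographic
# label sequence) ordering.
oracle_best_path <- function(graph, from, to) {
  edges <- graph$edges
  adj <- function(v) {
    rows <- edges$from == v | edges$to == v
    data.frame(other = ifelse(edges$from[rows] == v,
                              edges$to[rows], edges$from[rows]),
               d = edges$distance_A[rows], stringsAsFactors = FALSE)
  }
  paths <- list()
  walk <- function(v, visited, dists) {
    if (v == to) {
      paths[[length(paths) + 1L]] <<- list(labels = visited, dists = dists)
      return(invisible())
    }
    nb <- adj(v)
    for (k in seq_len(nrow(nb))) {
      if (!(nb$other[k] %in% visited))
        walk(nb$other[k], c(visited, nb$other[k]), c(dists, nb$d[k]))
    }
  }
  walk(from, from, numeric(0))
  if (length(paths) == 0L) return(NULL)
  score <- vapply(paths, function(p) max(p$dists), numeric(1))
  steps <- vapply(paths, function(p) length(p$dists), numeric(1))
  keep <- which(score == min(score))
  keep <- keep[steps[keep] == min(steps[keep])]
  seqs <- vapply(paths[keep], function(p) paste(p$labels, collapse = "\r"),
                 character(1))
  paths[[keep[order(seqs)[1]]]]
}

# FES-template chain with exact constructed edge-to-edge distances:
# consecutive steps of 14.0 A (A-B-C-D-E) plus a 19.0 A A-D shortcut.
# The [2Fe2S] template spans +/-1.35 A along x, so collinear placements
# 16.7 A apart give 14.0 A edges and the 21.7 A A-D pair gives 19.0 A;
# the out-of-plane kink keeps every other pair beyond 20 A.
chain_with_shortcut_layout <- function() {
  z1 <- sqrt(14^2 - 0.2^2)
  data.frame(kind = "fe2s2",
             x = c(0, 2.5, 19.2, 21.7, 38.4),
             y = 0,
             z = c(0, z1, z1, 0, 0))
}

make_chain_cofactors <- function() {
  f <- tempfile(fileext = ".pdb")
  make_toy_structure(chain_with_shortcut_layout(), f)
  identify_cofactors(parse_structure(f))
}
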