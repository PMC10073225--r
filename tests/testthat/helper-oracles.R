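# Independent oracles and fixture builders used across the suite.

# Random symmetric weighted network on n nodes. With dyadic = TRUE weights are
# powers of two, so shortest-path distances are exact in floating point and
# genuine ties between paths occur.
random_network <- function(n, density = 0.6, dyadic = FALSE) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  present <- runif(sum(ut)) < density
  vals <- if (dyadic) sample(c(0.5, 1, 2, 4), sum(ut), replace = TRUE)
          else runif(sum(ut), 0.2, 3)
  w[ut] <- vals * present
  w <- w + t(w)
  weighted_network(w, sprintf("r%02d", seq_len(n)))
}

# Enumerate every simple path between s and t and return each path with its
# total 1/weight distance. Exponential; only for tiny graphs.
enumerate_simple_paths <- function(w, s, t) {
  n <- nrow(w)
  out <- list()
  rec <- function(path, dist) {
    last <- path[length(path)]
    if (last == t) {
      out[[length(out) + 1]] <<- list(path = path, dist = dist)
      return(invisible())
    }
    for (nb in seq_len(n)) {
      if (w[last, nb] > 0 && !(nb %in% path)) {
        rec(c(path, nb), dist + 1 / w[last, nb])
      }
    }
  }
  rec(s, 0)
  out
}

# Brute-force betweenness (normalized by (n-1)(n-2)/2, fractional tie split)
# and per-node mean shortest-path distance over reachable partners.
oracle_path_metrics <- function(net, tie_tol = 1e-12) {
  w <- net$weights
  n <- nrow(w)
  bw <- numeric(n)
  dmat <- matrix(Inf, n, n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- enumerate_simple_paths(w, s, t)
      if (length(paths) == 0) next
      dists <- vapply(paths, `[[`, numeric(1), "dist")
      dmin <- min(dists)
      dmat[s, t] <- dmat[t, s] <- dmin
      minimal <- paths[dists <= dmin * (1 + tie_tol)]
      contrib <- numeric(n)
      for (p in minimal) {
        interior <- setdiff(p$path, c(s, t))
        contrib[interior] <- contrib[interior] + 1
      }
      bw <- bw + contrib / length(minimal)
    }
  }
  diag(dmat) <- NA
  apl <- apply(dmat, 1, function(row) {
    f <- row[is.finite(row)]
    if (length(f) == 0) NA_real_ else mean(f)
  })
  list(betweenness = bw / ((n - 1) * (n - 2) / 2), apl = unname(apl))
}

# Tiny labeled dataset with planted signal: first `n_inf` features carry a
# standardized group difference `d`, the rest are noise.
planted_table <- function(n0, n1, p, n_inf, d, seed) {
  withr::with_seed(seed, {
    label <- c(rep(0L, n0), rep(1L, n1))
    x <- matrix(rnorm((n0 + n1) * p), n0 + n1, p)
    if (n_inf > 0) x[label == 1L, seq_len(n_inf)] <-
      x[label == 1L, seq_len(n_inf), drop = FALSE] + d
    colnames(x) <- sprintf("f%03d", seq_len(p))
    dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("S%03d", seq_len(n0 + n1)),
                     label = label,
                     age = round(rnorm(n0 + n1, 32, 10), 1),
                     sex = stats::rbinom(n0 + n1, 1, 0.3),
                     diet = stats::rbinom(n0 + n1, 1, 0.35)),
      tibble::as_tibble(x)
    )
  })
}

# simple connected test network helpers
path_network <- function(weights = c(1, 1)) {
  n <- length(weights) + 1
  w <- matrix(0, n, n)
  for (i in seq_along(weights)) w[i, i + 1] <- w[i + 1, i] <- weights[i]
  weighted_network(w, letters[seq_len(n)])
}

complete_network <- function(n, weight = 1) {
  w <- matrix(weight, n, n)
  diag(w) <- 0
  weighted_network(w, letters[seq_len(n)])
}
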