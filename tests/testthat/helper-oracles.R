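# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use plain loops and none of the package's vectorized paths.

# Naive k-NN with the same deterministic tie rules: equal distances favour
# the lower reference index (stable order), tied votes favour label 0.
naive_knn_predict <- function(Xr, yr, Xq, k) {
  apply(as.matrix(Xq), 1, function(q) {
    d <- sqrt(rowSums(sweep(as.matrix(Xr), 2, q)^2))
    nn <- order(d)[seq_len(k)]
    if (sum(yr[nn]) * 2 > k) 1L else 0L
  })
}

naive_mu <- function(domain_i, domain_j, k) {
  pred <- naive_knn_predict(domain_j$X, domain_j$y, domain_i$X, k)
  mean(pred != domain_i$y)
}

# Double-loop recomputation of the disparity matrix, sharing only the
# diagonal split plumbing (same seeds) so exact equality is well-defined.
naive_disparity_matrix <- function(domains, k, train_fraction, seed) {
  M <- length(domains)
  D <- matrix(0, M, M)
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (i != j) next
    }
  }
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (i < j) {
        D[i, j] <- D[j, i] <- min(naive_mu(domains[[i]], domains[[j]], k),
                                  naive_mu(domains[[j]], domains[[i]], k))
      }
    }
    parts <- split_disjoint(domains[[i]], train_fraction,
                            seed = bcishift:::derive_seed(seed, 7L, i))
    D[i, i] <- naive_mu(parts$test, parts$train, k)
  }
  D
}

# A labeled domain with points on a rotated halfspace rule (angle in
# degrees), optional flips, standard-normal marginal.
make_rule_domain <- function(id, n, F_dim = 2, angle = 0, flip = 0,
                             sep = 0, offset = numeric(F_dim), scale = 1,
                             seed = 1) {
  withr::with_seed(seed, {
    u <- c(cos(angle * pi / 180), sin(angle * pi / 180),
           numeric(F_dim - 2))
    X <- matrix(rnorm(n * F_dim, sd = scale), ncol = F_dim)
    y0 <- as.integer(as.vector(X %*% u) > 0)
    X <- X + (y0 - 0.5) * sep * rep(u, each = n)
    X <- sweep(X, 2, offset, "+")
    y <- ifelse(runif(n) < flip, 1L - y0, y0)
    domain_sample(id, X, y)
  })
}

# Small hand-built feature table: 2 subjects x 2 sessions, n task rows per
# cell plus a few baseline rows per subject.
make_small_table <- function(n_cell = 20, n_baseline = 6, F_dim = 3,
                             seed = 1) {
  withr::with_seed(seed, {
    grid <- expand.grid(subject = c("S0", "S1"),
                        session = c("session1", "session2"),
                        stringsAsFactors = FALSE)
    task <- purrr::pmap_dfr(grid, function(subject, session) {
      X <- matrix(rnorm(n_cell * F_dim, mean = ifelse(subject == "S1", 1, 0)),
                  ncol = F_dim)
      colnames(X) <- sprintf("f%02d", seq_len(F_dim))
      dplyr::bind_cols(
        tibble::tibble(subject = subject, session = session, phase = "task",
                       label = ifelse(session == "session1", "low", "high")),
        tibble::as_tibble(X))
    })
    base <- purrr::map_dfr(c("S0", "S1"), function(s) {
      purrr::map_dfr(c("baseline1", "baseline2"), function(ph) {
        X <- matrix(rnorm(n_baseline * F_dim), ncol = F_dim)
        colnames(X) <- sprintf("f%02d", seq_len(F_dim))
        dplyr::bind_cols(
          tibble::tibble(subject = s, session = "session1", phase = ph,
                         label = NA_character_),
          tibble::as_tibble(X))
      })
    })
    validate_feature_table(dplyr::bind_rows(task, base))
  })
}

write_temp_table <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
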