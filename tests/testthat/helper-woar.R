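# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# Single-participant study with hand-set estimates per stage. `m` gives the
# model point for each image; its bin is looked up in the default scheme.
mini_study <- function(truth, est1, est2, est3 = est2, m,
                       participant_id = "p01", confidence = 3L,
                       likert = NULL, scheme = default_bin_scheme()) {
  n <- length(truth)
  stopifnot(length(est1) == n, length(est2) == n, length(est3) == n,
            length(m) == n)
  image_id <- sprintf("img%02d", seq_len(n))
  idx <- assign_bin(m, scheme)
  predictions <- tibble::tibble(
    image_id = image_id,
    bin_lo_weeks = scheme$lo[idx],
    bin_hi_weeks = scheme$hi[idx],
    point_weeks = m
  )
  mk_stage <- function(s, est) tibble::tibble(
    participant_id = participant_id, image_id = image_id, stage = s,
    true_ga_weeks = truth, estimate_weeks = est,
    confidence = rep_len(as.integer(confidence), n),
    time_sec = 10, features = if (s == 1L) "head_size" else ""
  )
  estimates <- dplyr::bind_rows(mk_stage(1L, est1), mk_stage(2L, est2),
                                mk_stage(3L, est3))
  study_table(estimates, predictions,
              likert = likert %||% woar:::empty_likert(), bin_scheme = scheme)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp_test <- function(x) pmin(pmax(x, 10), 45)

# A valid multi-participant study for validation-corruption tests.
small_valid_study <- function(seed = 42) {
  cfg <- simulation_config(n_participants = 2L, n_images = 6L)
  generate_study(cfg, seed)
}

# Literal step-by-step re-evaluation of the reliance-typing definitions,
# scalar at a time: the independent oracle for classify_reliance.
reliance_oracle <- function(y, p1, p2, m) {
  vapply(seq_along(y), function(i) {
    eps_p1 <- abs(p1[i] - y[i])
    eps_m <- abs(m[i] - y[i])
    delta1 <- abs(p1[i] - m[i])
    delta2 <- abs(p2[i] - m[i])
    R <- if (delta2 < delta1) 1L else 0L
    E_m <- if (eps_m < eps_p1) 1L else 0L
    if (R == E_m) "appropriate" else if (R == 0L && E_m == 1L) "under" else "over"
  }, character(1))
}

# Exhaustive sign-pattern enumeration for the signed-rank test (n <= ~12).
wilcoxon_brute_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  tol <- 1e-9
  min(1, 2 * min(mean(w_all <= w_obs + tol), mean(w_all >= w_obs - tol)))
}

# Exhaustive group-assignment enumeration for the rank-sum test.
mannwhitney_brute_p <- function(a, b) {
  n_a <- length(a); n <- n_a + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(n, n_a)
  u_all <- colSums(matrix(r[combos], nrow = n_a)) - n_a * (n_a + 1) / 2
  tol <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + tol), mean(u_all >= u_obs - tol)))
}
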