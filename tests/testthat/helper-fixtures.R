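# shared fixtures, all built in code

# a small thorax phantom for fast unit tests
test_phantom <- function(seed = 1, shape = c(64, 64, 64), ...) {
  generate_thorax_phantom(thorax_phantom_spec(shape = shape, seed = seed, ...))
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# matched_ratings built directly from per-case rating vectors:
# diseased = list of numeric rating vectors (one per diseased case, -Inf =
# unmarked), normal_fp = numeric vector of per-normal-case highest FP score
# (-Inf = no mark), extra_nl = optional tibble(case_id, score)
ratings_fixture <- function(diseased, normal_fp = numeric(),
                            extra_nl = NULL) {
  ids_d <- sprintf("d%02d", seq_along(diseased))
  ids_f <- sprintf("f%02d", seq_along(normal_fp))
  cases <- tibble::tibble(
    case_id = c(ids_d, ids_f),
    n_lesions = c(vapply(diseased, length, 0L), rep(0L, length(normal_fp))))
  lr <- do.call(rbind, lapply(seq_along(diseased), function(i) {
    z <- diseased[[i]]
    tibble::tibble(case_id = ids_d[i], lesion_id = seq_along(z),
                   weight = 1 / length(z), rating = z)
  }))
  nl <- tibble::tibble(case_id = ids_f[is.finite(normal_fp)],
                       score = normal_fp[is.finite(normal_fp)])
  if (!is.null(extra_nl)) nl <- rbind(nl, extra_nl)
  matched_ratings(lr, nl, cases)
}

# random small matched_ratings instance (seeded by the caller)
random_ratings <- function() {
  kn <- sample(1:4, 1); kf <- sample(1:2, 1)
  diseased <- lapply(seq_len(kn), function(i) {
    L <- sample(1:3, 1)
    ifelse(runif(L) < 0.3, -Inf, sample(1:5, L, replace = TRUE))
  })
  normal_fp <- ifelse(runif(kf) < 0.3, -Inf, sample(1:5, kf, replace = TRUE))
  extra <- if (runif(1) < 0.5)
    tibble::tibble(case_id = "d01", score = sample(1:5, 1))
  ratings_fixture(diseased, normal_fp, extra)
}
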