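# small in-code fixtures shared across test files

# hand-built choice records: subject, gender, p, x, choice
make_records <- function(subject, gender, p, x, choice) {
  validate_choices(data.frame(subject = subject, gender = gender, p = p,
                              x = x, choice = choice,
                              stringsAsFactors = FALSE),
                   warn_off_grid = FALSE)
}

# random valid record set on the nominal grid
random_records <- function(n, n_subjects = 3, seed = 1) {
  set.seed(seed)
  make_records(
    subject = sample.int(n_subjects, n, replace = TRUE),
    gender = sample(c("F", "M"), n, replace = TRUE),
    p = sample(seq(0.05, 0.9, by = 0.05), n, replace = TRUE),
    x = sample(0:49, n, replace = TRUE),
    choice = sample(0:1, n, replace = TRUE)
  )
}

# brute-force overlap <psi|pi_j> as a plain 4-component complex dot product,
# independent of the package's 2-component shortcut
brute_force_p <- function(state, prospects) {
  psi <- unclass(state)
  ov <- vapply(prospects, function(pr) {
    full <- complex(4)
    full[c(2 * pr$index - 1, 2 * pr$index)] <- pr$gamma
    sum(Conj(psi) * full)
  }, complex(1))
  Mod(ov)^2 / sum(Mod(ov)^2)
}

# exhaustive two-sample KS statistic: largest ECDF gap over all pooled points
brute_force_ks <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}
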