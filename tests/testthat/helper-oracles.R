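# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and stats::phyper / stats::pt where they stand
# in as the primary check).

# Exhaustive-enumeration hypergeometric upper tail: enumerate every
# size-ny subset of 1..N, count how many overlap {1..nx} in >= k members.
enum_overlap_p <- function(N, nx, ny, k) {
  if (ny == 0) return(as.numeric(k <= 0))
  subs <- utils::combn(N, ny)
  cnt <- colSums(subs <= nx)
  mean(cnt >= k)
}

# Upper-tail Student-t probability by numerical integration of the
# handwritten density (no stats::pt).
t_upper_tail_numint <- function(t, df) {
  dens <- function(x)
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  if (t >= 0)
    stats::integrate(dens, t, Inf, rel.tol = 1e-13)$value
  else
    1 - stats::integrate(dens, -Inf, t, rel.tol = 1e-13)$value
}

# Scalar Welch / pooled two-sample statistic computed with plain loops,
# independent of the vectorized implementation.
welch_oracle <- function(x, y, var_equal = FALSE) {
  n1 <- length(x); n2 <- length(y)
  m1 <- sum(x) / n1; m2 <- sum(y) / n2
  v1 <- sum((x - m1)^2) / (n1 - 1)
  v2 <- sum((y - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  list(t = t, df = df, p = t_upper_tail_numint(t, df))
}

# Small expression matrix around given case/control row values.
toy_em <- function(case_rows, control_rows) {
  stopifnot(nrow(case_rows) == nrow(control_rows))
  vals <- cbind(case_rows, control_rows)
  rownames(vals) <- sprintf("G%03d", seq_len(nrow(vals)))
  colnames(vals) <- c(sprintf("case_%d", seq_len(ncol(case_rows))),
                      sprintf("ctrl_%d", seq_len(ncol(control_rows))))
  expression_matrix(vals, rep(c("case", "control"),
                              c(ncol(case_rows), ncol(control_rows))))
}

# Write a tiny GMT file and return its path.
write_tmp_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
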