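# Classed conditions so callers can distinguish failure modes programmatically.
.gc_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "geneclock_error")))
}

.gc_check_name <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    .gc_stop(paste(what, "must be a non-empty string"), "geneclock_domain_error")
  }
  invisible(x)
}

# Fraction of the interval [t_1, t_n] during which x >= thr, with linear
# interpolation of the threshold crossings between samples.
.duty_fraction <- function(t, x, thr) {
  n <- length(t)
  if (n < 2L) return(as.numeric(x[1] >= thr))
  above <- x >= thr
  dt <- diff(t)
  x0 <- x[-n]; x1 <- x[-1]
  a0 <- above[-n]; a1 <- above[-1]
  frac <- numeric(n - 1L)
  frac[a0 & a1] <- 1
  cross <- xor(a0, a1)
  if (any(cross)) {
    # fraction of the sub-interval on the >= thr side of the crossing
    lam <- (thr - x0[cross]) / (x1[cross] - x0[cross])
    frac[cross] <- ifelse(a0[cross], lam, 1 - lam)
  }
  sum(frac * dt) / (t[n] - t[1])
}
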