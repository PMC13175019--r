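#' Voltage-clamp protocol for the isolated Kv4.3 current
#'
#' A sequence of voltage segments applied to the Kv4.3 gating equations alone.
#' Convenience constructors: [vc_activation_protocol()] (successively larger
#' depolarizing pulses from a hyperpolarized holding potential) and
#' [vc_recovery_protocol()] (two identical pulses separated by increasing
#' recovery intervals).
#'
#' @param holding_mv Holding potential (mV); gates start at steady state here.
#' @param segments Data frame with columns `v_mv`, `dur_ms` and a `label`
#'   column tagging segments of interest (e.g. `"pulse"`).
#' @return An object of class `vc_protocol`.
#' @export
vc_protocol <- function(holding_mv, segments) {
  stopifnot(is.data.frame(segments),
            all(c("v_mv", "dur_ms", "label") %in% names(segments)))
  if (any(segments$dur_ms <= 0)) stop("segment durations must be > 0", call. = FALSE)
  structure(list(holding_mv = holding_mv, segments = segments),
            class = "vc_protocol")
}

#' @rdname vc_protocol
#' @param test_mv Test-pulse potentials (mV).
#' @param pulse_ms Pulse duration (ms).
#' @param inter_ms Inter-pulse interval at holding (ms).
#' @export
vc_activation_protocol <- function(holding_mv = -80,
                                   test_mv = seq(-60, 20, by = 10),
                                   pulse_ms = 1500, inter_ms = 2000) {
  segs <- do.call(rbind, lapply(seq_along(test_mv), function(i) {
    rbind(data.frame(v_mv = test_mv[i], dur_ms = pulse_ms,
                     label = paste0("pulse", i)),
          data.frame(v_mv = holding_mv, dur_ms = inter_ms, label = "hold"))
  }))
  vc_protocol(holding_mv, segs)
}

#' @rdname vc_protocol
#' @param pulse_mv Pulse potential (mV); the paired-pulse recovery protocol
#'   applies two 60 mV pulses from a -100 mV holding potential (i.e. to -40 mV).
#' @param interval_ms Recovery interval between the two pulses (ms).
#' @export
vc_recovery_protocol <- function(holding_mv = -100, pulse_mv = -40,
                                 pulse_ms = 1000, interval_ms = 100) {
  segs <- rbind(
    data.frame(v_mv = pulse_mv, dur_ms = pulse_ms, label = "pulse1"),
    data.frame(v_mv = holding_mv, dur_ms = interval_ms, label = "recovery"),
    data.frame(v_mv = pulse_mv, dur_ms = pulse_ms, label = "pulse2"))
  vc_protocol(holding_mv, segs)
}

#' Simulate the Kv4.3 current under voltage clamp
#'
#' Integrates only the Kv4.3 gating equations under a clamped, piecewise
#' constant voltage. Within each segment the voltage is constant, so each gate
#' relaxes exponentially toward its steady state in closed form; the current
#' is evaluated on a regular time grid.
#'
#' @param kv4 A [kv4_params()] object.
#' @param protocol A [vc_protocol()].
#' @param dt Sampling interval of the returned trace (ms).
#' @return A data frame of class `vc_trace`: `time_ms`, `v_mv`, `i_pa`,
#'   `label` (segment tag).
#' @export
simulate_voltage_clamp <- function(kv4, protocol, dt = 0.1) {
  stopifnot(inherits(kv4, "kv4_params"), inherits(protocol, "vc_protocol"))
  hold <- protocol$holding_mv
  p <- boltzmann_ss(hold, kv4$activation)
  qs <- qf <- boltzmann_ss(hold, kv4$inactivation)
  out <- vector("list", nrow(protocol$segments))
  t0 <- 0
  for (i in seq_len(nrow(protocol$segments))) {
    v <- protocol$segments$v_mv[i]
    dur <- protocol$segments$dur_ms[i]
    tt <- seq(0, dur, by = dt)
    p_inf <- boltzmann_ss(v, kv4$activation)
    q_inf <- boltzmann_ss(v, kv4$inactivation)
    tau_p <- tau_sigmoid(v, kv4$activation_tau)
    tau_s <- tau_sigmoid(v, kv4$tau_slow)
    tau_f <- tau_sigmoid(v, kv4$tau_fast)
    pt <- p_inf + (p - p_inf) * exp(-tt / tau_p)
    qst <- q_inf + (qs - q_inf) * exp(-tt / tau_s)
    qft <- q_inf + (qf - q_inf) * exp(-tt / tau_f)
    ii <- kv4$g_max * pt^3 * (kv4$f_s * qst + (1 - kv4$f_s) * qft) * (kv4$e_k - v)
    out[[i]] <- data.frame(time_ms = t0 + tt, v_mv = v, i_pa = ii,
                           label = protocol$segments$label[i])
    p <- pt[length(tt)]; qs <- qst[length(tt)]; qf <- qft[length(tt)]
    t0 <- t0 + dur
  }
  structure(do.call(rbind, out), class = c("vc_trace", "data.frame"))
}

#' Fraction of slow inactivation from a decaying current trace
#'
#' Fits a two-exponential decay with offset,
#' `|I|(t) = a_s exp(-t/tau_s) + a_f exp(-t/tau_f) + c`, to the decay phase of
#' a voltage-clamp current (time constants seeded at 250 ms and 45 ms,
#' amplitudes constrained non-negative) and returns the amplitude fraction of
#' the slow component, `a_s / (a_s + a_f)`.
#'
#' @param trace A data frame with columns `time_ms` and `i_pa` covering one
#'   depolarizing pulse (e.g. one `pulse` segment of
#'   [simulate_voltage_clamp()] output).
#' @return Fraction of slow inactivation in `[0, 1]`.
#' @export
measure_fraction_slow <- function(trace) {
  stopifnot(all(c("time_ms", "i_pa") %in% names(trace)))
  amp <- abs(trace$i_pa)
  ipk <- which.max(amp)
  if (ipk >= nrow(trace) - 10) stop("input current does not decay", call. = FALSE)
  tt <- trace$time_ms[ipk:nrow(trace)] - trace$time_ms[ipk]
  yy <- amp[ipk:nrow(trace)]
  if (yy[length(yy)] > 0.95 * yy[1]) stop("input current does not decay", call. = FALSE)
  a0 <- max(yy) - min(yy)
  df <- data.frame(t = tt, y = yy)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ as_ * exp(-t / ts_) + af_ * exp(-t / tf_) + c_,
                      data = df,
                      start = list(as_ = a0 / 2, ts_ = 250, af_ = a0 / 2,
                                   tf_ = 45, c_ = min(yy)),
                      lower = c(0, 60, 0, 5, 0),
                      upper = c(Inf, 2000, Inf, 60, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (!inherits(fit, "error")) {
    cf <- stats::coef(fit)
    return(unname(cf["as_"] / (cf["as_"] + cf["af_"])))
  }
  # degenerate decays (one amplitude ~0) make the free-tau fit singular;
  # fall back to non-negative amplitudes on a fixed-tau basis (Table values)
  basis <- cbind(slow = exp(-tt / 250), fast = exp(-tt / 45), offset = 1)
  coefs <- nnls2(basis, yy)
  if (coefs["slow"] + coefs["fast"] <= 0) {
    stop("double-exponential fit failed: no decaying component", call. = FALSE)
  }
  unname(coefs["slow"] / (coefs["slow"] + coefs["fast"]))
}

# tiny non-negative least squares by subset enumeration (few columns only)
nnls2 <- function(X, y) {
  p <- ncol(X)
  best <- NULL
  for (mask in seq_len(2^p - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    cf <- tryCatch(stats::coef(stats::lm.fit(X[, idx, drop = FALSE], y)),
                   error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf)) || any(cf < 0)) next
    full <- stats::setNames(numeric(p), colnames(X))
    full[idx] <- cf
    rss <- sum((y - X %*% full)^2)
    if (is.null(best) || rss < best$rss) best <- list(coef = full, rss = rss)
  }
  if (is.null(best)) stats::setNames(numeric(p), colnames(X)) else best$coef
}

#' Recovery from inactivation (paired-pulse ratio curve)
#'
#' For each recovery interval, simulates a paired-pulse protocol and returns
#' the ratio of the second-pulse peak current to the first-pulse peak
#' (peaks measured as the extremum of |I| within each pulse).
#'
#' @param kv4 A [kv4_params()] object.
#' @param intervals_ms Recovery intervals (ms), sorted ascending.
#' @param holding_mv,pulse_mv,pulse_ms Protocol parameters, see
#'   [vc_recovery_protocol()].
#' @param dt Sampling interval (ms).
#' @return A data frame: `interval_ms`, `ratio` (I/Imax in `[0, 1]`).
#' @export
recovery_curve <- function(kv4, intervals_ms = c(25, 50, 100, 1000),
                           holding_mv = -100, pulse_mv = -40, pulse_ms = 1000,
                           dt = 0.1) {
  if (is.unsorted(intervals_ms)) stop("intervals must be sorted ascending", call. = FALSE)
  ratios <- vapply(intervals_ms, function(iv) {
    pr <- vc_recovery_protocol(holding_mv, pulse_mv, pulse_ms, iv)
    tr <- simulate_voltage_clamp(kv4, pr, dt = dt)
    pk1 <- max(abs(tr$i_pa[tr$label == "pulse1"]))
    pk2 <- max(abs(tr$i_pa[tr$label == "pulse2"]))
    if (pk1 == 0) stop("zero first-pulse peak", call. = FALSE)
    pk2 / pk1
  }, numeric(1))
  data.frame(interval_ms = intervals_ms, ratio = ratios)
}
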