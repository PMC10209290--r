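# Independent reference implementations used as oracles, written as literal
# step-by-step procedures so they stay independent of the package's
# vectorised code paths.

# reference greedy minimum-separation selection: explicit repeated deletion
oracle_min_sep <- function(P, L, fs, min_sep_s = 0.3) {
  m <- round(min_sep_s * fs)
  kept_P <- numeric(0); kept_L <- integer(0)
  while (length(P)) {
    best <- which(P == max(P))
    best <- best[which.min(L[best])]          # earlier index wins ties
    kept_P <- c(kept_P, P[best]); kept_L <- c(kept_L, L[best])
    far <- abs(L - L[best]) >= m
    P <- P[far]; L <- L[far]
  }
  ord <- order(kept_L)
  list(P = kept_P[ord], L = kept_L[ord])
}

# reference candidate augmentation: a straight reading of the four steps
# (remove candidates from the full maxima set; interpolate the remainder;
# take its spaced maxima, skipping existing candidate positions; merge)
oracle_augment <- function(P_A, L_A, P_C, L_C, fs, siglen,
                           n_iter = 3, min_sep_s = 0.3) {
  interp_full <- function(xa, ya) {
    xs <- 0:(siglen - 1)
    out <- numeric(siglen)
    inside <- xs >= xa[1] & xs <= xa[length(xa)]
    out[inside] <- if (length(xa) == 2)
      stats::approx(xa, ya, xs[inside])$y
    else pracma::pchip(xa, ya, xs[inside])
    out[xs < xa[1]] <- ya[1]
    out[xs > xa[length(xa)]] <- ya[length(ya)]
    out
  }
  find_maxima <- function(x) {
    idx <- integer(0)
    i <- 2L
    while (i <= length(x) - 1L) {
      if (x[i] > x[i - 1L]) {
        j <- i
        while (j < length(x) && x[j + 1L] == x[j]) j <- j + 1L
        if (j < length(x) && x[j + 1L] < x[j]) idx <- c(idx, i)
        i <- j + 1L
      } else i <- i + 1L
    }
    idx - 1L
  }
  aux_P <- P_C; aux_L <- L_C
  pms_first <- pms_last <- list(P = numeric(0), L = integer(0))
  for (it in seq_len(n_iter)) {
    drop <- L_A %in% aux_L
    P_A <- P_A[!drop]; L_A <- L_A[!drop]
    if (length(L_A) < 2) break
    mid <- interp_full(L_A, P_A)
    ml <- find_maxima(mid)
    sel <- oracle_min_sep(mid[ml + 1L], ml, fs, min_sep_s)
    new <- !(sel$L %in% aux_L)
    pms_last <- list(P = sel$P[new], L = sel$L[new])
    if (it == 1) pms_first <- pms_last
    aux_P <- c(aux_P, pms_last$P); aux_L <- c(aux_L, pms_last$L)
    ord <- order(aux_L)
    aux_P <- aux_P[ord]; aux_L <- aux_L[ord]
  }
  list(aux = list(P = aux_P, L = aux_L),
       pms = pms_first, pms_last = pms_last)
}

# default synthetic fixture used across detector tests
fixture_ecg <- function(fs = 250, duration_s = 30, hr_bpm = 70, seed = 11, ...) {
  synth_ecg(synth_config(fs = fs, duration_s = duration_s, hr_bpm = hr_bpm,
                         seed = seed, ...))
}

fixture_ppg <- function(fs = 128, duration_s = 30, hr_bpm = 70, seed = 12, ...) {
  synth_ppg(synth_config(fs = fs, duration_s = duration_s, hr_bpm = hr_bpm,
                         seed = seed, ...))
}

# run the packaged CLI script in a fresh R process with the test library path
run_cli <- function(args, input = NULL) {
  script <- system.file("cli", "webeat.R", package = "webeat")
  stopifnot(nzchar(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(script, args),
    stdout = TRUE, stderr = TRUE, input = input,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  status <- attr(out, "status")
  list(output = as.character(out), status = if (is.null(status)) 0L else status)
}
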