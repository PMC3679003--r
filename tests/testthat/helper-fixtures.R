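# Shared fixture builders (all generated in code; no stored data).

# corrected-provenance trace built from values on a 15-s grid
correctedTrace <- function(values, dt = 15, well = "w1") {
  ImpedanceTrace(well, seq(0, by = dt, length.out = length(values)), values,
                 provenance = "corrected")
}

# symmetric triangle of given peak height spanning [a, b], zero outside,
# sampled on a grid that hits the vertices
triangleValues <- function(times, a, b, height) {
  mid <- (a + b) / 2
  up <- times >= a & times <= mid
  dn <- times > mid & times <= b
  v <- numeric(length(times))
  v[up] <- height * (times[up] - a) / (mid - a)
  v[dn] <- height * (b - times[dn]) / (b - mid)
  v
}

# noiseless generator parameter set
quietImpedanceParams <- function(...) {
  impedanceGenParams(noiseSd = 0, gainSd = 0, driftPerHour = 0, ...)
}

quietEphysParams <- function(...) {
  ephysGenParams(restingSd = 0, ouSd = 0, ...)
}

# constructed recording from a Vm vector at 10 Hz around a 60-s pulse
makeRecording <- function(vm, dt = 0.1, onset = 120, duration = 60,
                          cell = "c1") {
  times <- seq(0, by = dt, length.out = length(vm))
  EphysRecording(cell, times, vm,
                 stimulusProtocol(lightPulse(onset, duration, flux = 2.53e16)),
                 1 / dt)
}

# brute-force Mann-Whitney: U by the pair-counting definition, exact
# two-sided p by enumerating all group assignments of the pooled values.
# Independent of the package's rank-based implementation.
bruteForceMW <- function(a, b) {
  uOf <- function(x, y) {
    s <- 0
    for (xi in x) s <- s + sum(xi > y) + 0.5 * sum(xi == y)
    s
  }
  u <- uOf(a, b)
  pooled <- c(a, b)
  idx <- utils::combn(length(pooled), length(a))
  uAll <- apply(idx, 2, function(k) uOf(pooled[k], pooled[-k]))
  p <- min(1, 2 * min(mean(uAll <= u + 1e-9), mean(uAll >= u - 1e-9)))
  list(u = u, p = p)
}

# quadratic-space affine-gap global alignment score, written directly from
# the three-state recurrence with per-cell loops; independent oracle for
# globalAlign().
slowAlignScore <- function(q, r, gapOpen = 10, gapExt = 1) {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  sm <- get("BLOSUM62", envir = e)
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  n <- length(qs); m <- length(rs)
  M <- Ix <- Iy <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(gapOpen + i * gapExt)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(gapOpen + j * gapExt)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + sm[qs[i], rs[j]]
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - gapOpen - gapExt,
                            Ix[i, j + 1] - gapExt)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - gapOpen - gapExt,
                            Iy[i + 1, j] - gapExt)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

randomPeptide <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
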