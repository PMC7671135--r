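# Independent brute-force oracles used by several test files.

# 6-connected erosion by direct neighbourhood inspection
brute_erode <- function(x) {
  d <- dim(x)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!x[i, j, k]) next
    nb <- TRUE
    for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      p <- c(i, j, k) + off
      if (any(p < 1) || any(p > d) || !x[p[1], p[2], p[3]]) { nb <- FALSE; break }
    }
    out[i, j, k] <- nb
  }
  out
}

# cumulative turning angle by explicit segment-pair loop
brute_turning <- function(pts) {
  s <- diff(pts)
  u <- s / sqrt(rowSums(s^2))
  tot <- 0
  for (i in seq_len(nrow(u) - 1))
    tot <- tot + acos(min(max(sum(u[i, ] * u[i + 1, ]), -1), 1))
  tot * 180 / pi
}

# run the bundled CLI in a child R process with the test library visible
run_cli <- function(args, env_extra = character()) {
  script <- system.file("cli", "myotract.R", package = "myotract")
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  out <- suppressWarnings(
    system2(rscript, c(shQuote(script), args), stdout = TRUE, stderr = TRUE,
            env = c(paste0("R_LIBS=", libs), env_extra)))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
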