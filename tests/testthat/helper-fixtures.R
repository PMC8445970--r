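# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# n molecules, one perfectly separating feature (f_sep) plus pure noise.
makeSeparableDataset <- function(n = 60L, nNoise = 4L, posFrac = 1 / 3,
                                 seed = 1L, sepName = "f_sep") {
  set.seed(seed)
  nPos <- round(posFrac * n)
  pos <- seq_len(n) %in% sample.int(n, nPos)
  X <- matrix(rnorm(n * (nNoise + 1L)), n, nNoise + 1L)
  X[, 1L] <- ifelse(pos, abs(X[, 1L]) + 1, -abs(X[, 1L]) - 1)
  colnames(X) <- c(sepName,
                   if (nNoise > 0L) paste0("noise", seq_len(nNoise)))
  rownames(X) <- paste0("M", seq_len(n))
  ds <- DescriptorSet(X, sourceNote = "fixture: separable")
  joinLabels(ds, setNames(ifelse(pos, "pos", "neg"), rownames(X)), "pos")
}

# labeled dataset with given class counts and pure-noise features
makeNoiseDataset <- function(nPos, nNeg, p = 6L, seed = 1L) {
  set.seed(seed)
  n <- nPos + nNeg
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("M", seq_len(n)), paste0("f", seq_len(p))))
  lab <- sample(c(rep("pos", nPos), rep("neg", nNeg)))
  ds <- DescriptorSet(X, sourceNote = "fixture: noise")
  joinLabels(ds, setNames(lab, rownames(X)), "pos")
}

writeTempCSV <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
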