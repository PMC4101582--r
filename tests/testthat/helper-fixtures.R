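# shared fixtures, all built in code

# small labelled panel with a known differential channel
toyPanel <- function(seed = 1, n1 = 6, n2 = 6, nc = 16) {
  set.seed(seed)
  x <- matrix(rnorm(nc * (n1 + n2)), n1 + n2, nc)
  x[(n1 + 1):(n1 + n2), 4] <- x[(n1 + 1):(n1 + n2), 4] + 10
  SpectraMatrix(x, mz = 100 + seq_len(nc),
                labels = rep(c("ctrl", "case"), c(n1, n2)))
}

# hand-built linear SVM with a prescribed hyperplane; the two synthetic
# support vectors +-w/2 with alphas 1 satisfy every SvmModel invariant
makeToySvm <- function(w, b, classMap) {
  sv <- rbind(w / 2, -w / 2)
  new("SvmModel", alphas = c(1, 1), supportVectors = sv,
      supportLabels = c(1, -1), bias = b, cost = 1e6, w = as.numeric(w),
      classMap = classMap)
}

writeToyMatrixFile <- function(path, withLabels = FALSE, sep = ",") {
  header <- paste(c("id", "100", "105.5", "110", "120", "121", "130", "131",
                    "140", if (withLabels) "label"), collapse = sep)
  rows <- c(
    paste(c("s1", "1", "2", "3", "4", "5", "6", "7", "8",
            if (withLabels) "ctrl"), collapse = sep),
    paste(c("s2", "0.5", "0.25", "0", "-1", "2.5", "3", "1", "0",
            if (withLabels) "case"), collapse = sep),
    paste(c("s3", "9", "8", "7", "6", "5", "4", "3", "2",
            if (withLabels) "case"), collapse = sep))
  writeLines(c(header, rows), path)
  path
}
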