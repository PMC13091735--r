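# Independent sum-of-squares oracle for the two-way within design: explicit
# nested sums over cell/marginal means, no shared code with the package.
oracle_ss <- function(cube) {
  n <- dim(cube)[1]; a <- dim(cube)[2]; b <- dim(cube)[3]
  gm <- mean(cube)
  ss <- list(A = 0, B = 0, AB = 0, AS = 0, BS = 0, ABS = 0)
  m_s <- sapply(1:n, function(s) mean(cube[s, , ]))
  m_a <- sapply(1:a, function(i) mean(cube[, i, ]))
  m_b <- sapply(1:b, function(j) mean(cube[, , j]))
  for (i in 1:a) ss$A <- ss$A + n * b * (m_a[i] - gm)^2
  for (j in 1:b) ss$B <- ss$B + n * a * (m_b[j] - gm)^2
  for (i in 1:a) for (j in 1:b) {
    ss$AB <- ss$AB + n * (mean(cube[, i, j]) - m_a[i] - m_b[j] + gm)^2
  }
  for (s in 1:n) for (i in 1:a) {
    ss$AS <- ss$AS + b * (mean(cube[s, i, ]) - m_s[s] - m_a[i] + gm)^2
  }
  for (s in 1:n) for (j in 1:b) {
    ss$BS <- ss$BS + a * (mean(cube[s, , j]) - m_s[s] - m_b[j] + gm)^2
  }
  for (s in 1:n) for (i in 1:a) for (j in 1:b) {
    ss$ABS <- ss$ABS + (cube[s, i, j] - mean(cube[s, i, ]) -
                          mean(cube[s, , j]) - mean(cube[, i, j]) +
                          m_s[s] + m_a[i] + m_b[j] - gm)^2
  }
  ss
}

grid_to_df <- function(cube) {
  d <- dim(cube)
  df <- expand.grid(participant = factor(1:d[1]), A = factor(1:d[2]),
                    B = factor(1:d[3]))
  df$value <- as.numeric(cube)
  df
}
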