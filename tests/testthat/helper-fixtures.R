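# Shared helpers: tiny graphs and brute-force oracles used across tests.

# brute-force AUROC: concordant pairs + half ties over pos x neg
oracleAUC <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# brute-force AP: threshold sweep over distinct score values
oracleAP <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  rPrev <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / sum(labels == 1)
    ap <- ap + (rec - rPrev) * prec
    rPrev <- rec
  }
  ap
}

# brute-force accuracy from confusion counts
oracleACC <- function(labels, scores, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  (tp + tn) / (tp + tn + fp + fn)
}

# brute-force kNN adjacency with the documented stable tie rule
oracleKnn <- function(D, k) {
  n <- nrow(D)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    nb <- order(d)[seq_len(k)]
    A[i, nb] <- 1
  }
  A <- 1 * (A | t(A))
  diag(A) <- 0
  A
}

# quadruple-loop Gromov-Wasserstein cost oracle
oracleGW <- function(DX, DY, P) {
  n <- nrow(DX); m <- nrow(DY)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    for (k in seq_len(m)) for (l in seq_len(m))
      s <- s + (DX[i, j] - DY[k, l])^2 * P[i, k] * P[j, l]
  s
}

rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

angleOf <- function(R) atan2(R[2, 1], R[1, 1]) * 180 / pi

# small planted-structure tissue for quick training tests
smallTissue <- function(seed = 0, nCells = 80) {
  simulateTissue(nCells = nCells, nGenes = 30, nCommunities = 3,
                 nNeighbors = 4, seed = seed)
}

writeTempTSV <- function(df) {
  tf <- tempfile(fileext = ".tsv")
  write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  tf
}
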