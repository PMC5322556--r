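# Independent alignment oracles, layered:
#  - enum_*: full enumeration of every alignment (DP-free), feasible only for
#    tiny strings; scores computed by an independent run-aware scorer.
#  - rdp_*: plain R dynamic programs written top-down/bottom-up, independent
#    of the package's C++ implementation; validated against enum_* and used
#    for larger random pairs.

oracle_score <- function(x, y, sc) {
  if (x == "N" || y == "N") return(0L)
  if (x == y) sc$match else sc$mismatch
}

# score an alignment given as a vector of column codes over S (substitution),
# B (gap in b, consumes a), A (gap in a, consumes b)
score_alignment_cols <- function(cols, a, b, sc) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  i <- 0L; j <- 0L; total <- 0L; run <- ""
  for (col in cols) {
    if (col == "S") {
      i <- i + 1L; j <- j + 1L
      total <- total + oracle_score(ca[i], cb[j], sc)
      run <- ""
    } else {
      cost <- if (run == col) sc$gap_extend else sc$gap_open
      if (col == "B") i <- i + 1L else j <- j + 1L
      total <- total + cost
      run <- col
    }
  }
  total
}

# all global alignments of a vs b as column-code vectors
enum_alignments <- function(n, m) {
  rec <- function(i, j) {
    if (i == n && j == m) return(list(character(0)))
    out <- list()
    if (i < n && j < m) out <- c(out, lapply(rec(i + 1L, j + 1L), function(x) c("S", x)))
    if (i < n) out <- c(out, lapply(rec(i + 1L, j), function(x) c("B", x)))
    if (j < m) out <- c(out, lapply(rec(i, j + 1L), function(x) c("A", x)))
    out
  }
  rec(0L, 0L)
}

enum_global_score <- function(a, b, sc) {
  alns <- enum_alignments(nchar(a), nchar(b))
  max(vapply(alns, score_alignment_cols, numeric(1), a = a, b = b, sc = sc))
}

# local score by enumeration: best global score over all substring pairs, or 0
enum_local_score <- function(a, b, sc) {
  best <- 0
  n <- nchar(a); m <- nchar(b)
  for (i1 in seq_len(n)) for (i2 in i1:n) {
    sa <- substr(a, i1, i2)
    for (j1 in seq_len(m)) for (j2 in j1:m) {
      best <- max(best, enum_global_score(sa, substr(b, j1, j2), sc))
    }
  }
  best
}

# memoized top-down global DP with affine gaps (independent formulation:
# state = previous column type)
rdp_global_score <- function(a, b, sc) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ca); m <- length(cb)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, oracle_score(ca[i], cb[j], sc) + rec(i + 1L, j + 1L, "S"))
    }
    if (i <= n) {
      best <- max(best, (if (prev == "B") sc$gap_extend else sc$gap_open) +
                    rec(i + 1L, j, "B"))
    }
    if (j <= m) {
      best <- max(best, (if (prev == "A") sc$gap_extend else sc$gap_open) +
                    rec(i, j + 1L, "A"))
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, "S")
}

# bottom-up local DP in plain R (linear or affine via two extra rows)
rdp_local_score <- function(a, b, sc) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  S <- matrix(0, n + 1, m + 1)
  GX <- matrix(NEG, n + 1, m + 1)  # gap consuming a
  GY <- matrix(NEG, n + 1, m + 1)  # gap consuming b
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    GX[i + 1, j + 1] <- max(S[i, j + 1] + sc$gap_open, GX[i, j + 1] + sc$gap_extend)
    GY[i + 1, j + 1] <- max(S[i + 1, j] + sc$gap_open, GY[i + 1, j] + sc$gap_extend)
    sub <- S[i, j] + oracle_score(ca[i], cb[j], sc)
    S[i + 1, j + 1] <- max(0, sub, GX[i + 1, j + 1], GY[i + 1, j + 1])
    best <- max(best, S[i + 1, j + 1])
  }
  best
}

random_pair <- function(max_len, min_len = 1L) {
  n <- sample(min_len:max_len, 1L)
  m <- sample(min_len:max_len, 1L)
  c(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    paste(sample(c("A", "C", "G", "T"), m, replace = TRUE), collapse = ""))
}
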