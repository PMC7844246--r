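# exhaustive-enumeration oracle mirroring the documented path semantics:
# paths choose one candidate on a subset of the frame range, consecutive
# chosen frames at most max_skip+1 apart (also at the range edges), each
# unchosen frame in the range costs skip_penalty, transitions admissible
# when the center displacement is within radius x gap
viterbi_oracle_score <- function(cpf, radius, skip_penalty = log(0.05),
                                 max_skip = 2) {
  nz <- which(!vapply(cpf, function(d) is.null(d) || nrow(d) == 0, TRUE))
  f0 <- min(nz); f1 <- max(nz)
  frames <- f0:f1
  nf <- length(frames)
  center <- function(d, i) c((d$x0[i] + d$x1[i]) / 2, (d$y0[i] + d$y1[i]) / 2)
  best <- -Inf
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), nf))
  for (si in seq_len(nrow(subsets))) {
    sel <- which(unlist(subsets[si, ]))
    if (length(sel) == 0) next
    if (any(vapply(frames[sel], function(f)
      is.null(cpf[[f]]) || nrow(cpf[[f]]) == 0, TRUE))) next
    if (sel[1] - 1 > max_skip) next
    if (nf - sel[length(sel)] > max_skip) next
    if (length(sel) > 1 && any(diff(sel) > max_skip + 1)) next
    counts <- vapply(frames[sel], function(f) nrow(cpf[[f]]), 0L)
    choice <- rep(1L, length(sel))
    repeat {
      lp <- 0; ok <- TRUE
      for (j in seq_along(sel)) {
        d <- cpf[[frames[sel[j]]]]
        lp <- lp + log(d$p_human[choice[j]])
        if (j > 1) {
          dprev <- cpf[[frames[sel[j - 1]]]]
          i0 <- choice[j - 1]
          r <- if (is.null(radius))
            1.5 * sqrt((dprev$x1[i0] - dprev$x0[i0])^2 +
                       (dprev$y1[i0] - dprev$y0[i0])^2)
          else radius
          gap <- sel[j] - sel[j - 1]
          dd <- sqrt(sum((center(d, choice[j]) - center(dprev, i0))^2))
          if (dd > r * gap) { ok <- FALSE; break }
        }
      }
      if (ok) {
        sc <- lp + skip_penalty * (nf - length(sel))
        if (sc > best) best <- sc
      }
      j <- length(choice)
      while (j >= 1 && choice[j] == counts[j]) { choice[j] <- 1L; j <- j - 1 }
      if (j == 0) break
      choice[j] <- choice[j] + 1L
    }
  }
  best
}

rand_instance <- function(seed) {
  set.seed(seed)
  nf <- sample(2:5, 1)
  lapply(seq_len(nf), function(f) {
    m <- sample(0:4, 1)
    if (f == 1 && m == 0) m <- 1  # ensure some candidate exists
    if (m == 0) return(NULL)
    x0 <- runif(m, 0, 80); y0 <- runif(m, 0, 60)
    data.frame(x0 = x0, y0 = y0, x1 = x0 + runif(m, 5, 20),
               y1 = y0 + runif(m, 10, 30),
               p_human = runif(m, 0.05, 0.99))
  })
}
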