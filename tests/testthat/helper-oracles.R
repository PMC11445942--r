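# Independent brute-force oracles shared by unit and acceptance tests.

# Independent rubric-lookup oracle, written as literal nested conditions.
oracle_sofa <- function(pf = NA, plt = NA, bili = NA, map = NA, gcs = NA,
                        cr = NA, dopa = 0, norepi = 0, epi = 0, dobu = 0,
                        vent = FALSE) {
  resp <- if (is.na(pf)) 0
  else if (pf >= 400) 0
  else if (pf >= 300) 1
  else if (pf >= 200) 2
  else if (!vent) 2
  else if (pf >= 100) 3
  else 4
  coag <- if (is.na(plt)) 0
  else if (plt >= 150) 0 else if (plt >= 100) 1 else if (plt >= 50) 2
  else if (plt >= 20) 3 else 4
  hep <- if (is.na(bili)) 0
  else if (bili < 1.2) 0 else if (bili < 2) 1 else if (bili < 6) 2
  else if (bili < 12) 3 else 4
  cardio <- 0
  if (!is.na(map) && map < 70) cardio <- 1
  if ((dopa > 0 && dopa <= 5) || dobu > 0) cardio <- max(cardio, 2)
  if ((dopa > 5) || (norepi > 0 && norepi <= 0.1) || (epi > 0 && epi <= 0.1))
    cardio <- max(cardio, 3)
  if (dopa > 15 || norepi > 0.1 || epi > 0.1) cardio <- max(cardio, 4)
  cns <- if (is.na(gcs)) 0
  else if (gcs >= 15) 0 else if (gcs >= 13) 1 else if (gcs >= 10) 2
  else if (gcs >= 6) 3 else 4
  renal <- if (is.na(cr)) 0
  else if (cr < 1.2) 0 else if (cr < 2) 1 else if (cr < 3.5) 2
  else if (cr < 5) 3 else 4
  c(respiration = resp, coagulation = coag, hepatic = hep,
    cardiovascular = cardio, cns = cns, renal = renal,
    total = resp + coag + hep + cardio + cns + renal)
}


# Brute-force definitional oracles for the three internal-validity indices.
oracle_silhouette <- function(x, cl) {
  n <- nrow(x)
  s <- numeric(n)
  for (i in 1:n) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(sapply(own, function(j) sqrt(sum((x[i, ] - x[j, ])^2))))
    b <- min(sapply(setdiff(unique(cl), cl[i]), function(g) {
      mem <- which(cl == g)
      mean(sapply(mem, function(j) sqrt(sum((x[i, ] - x[j, ])^2))))
    }))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
oracle_ch <- function(x, cl) {
  n <- nrow(x); ks <- unique(cl); k <- length(ks)
  g <- colMeans(x)
  B <- 0; W <- 0
  for (j in ks) {
    mem <- x[cl == j, , drop = FALSE]
    c_j <- colMeans(mem)
    B <- B + nrow(mem) * sum((c_j - g)^2)
    W <- W + sum(sweep(mem, 2, c_j)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}
oracle_db <- function(x, cl) {
  ks <- sort(unique(cl)); k <- length(ks)
  cent <- t(sapply(ks, function(j) colMeans(x[cl == j, , drop = FALSE])))
  s <- sapply(seq_len(k), function(j)
    mean(sqrt(rowSums(sweep(x[cl == ks[j], , drop = FALSE], 2, cent[j, ])^2))))
  mean(sapply(seq_len(k), function(j)
    max(sapply(setdiff(seq_len(k), j), function(l)
      (s[j] + s[l]) / sqrt(sum((cent[j, ] - cent[l, ])^2))))))
}


# Hand product-limit oracle: S(t) steps down by (1 - d_i / n_i) at each
# distinct death time.
oracle_km <- function(time, event, t_eval) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(t_eval))
  for (i in seq_along(t_eval)) {
    s <- 1
    for (d in ts[ts <= t_eval[i]]) {
      n_risk <- sum(time >= d)
      n_dead <- sum(time == d & event == 1)
      s <- s * (1 - n_dead / n_risk)
    }
    out[i] <- s
  }
  out
}

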