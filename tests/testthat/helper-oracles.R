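# Independent naive oracles: one scalar-loop expression per measure,
# written directly from the printed formulas with no code shared with the
# package's evaluator. `k` is the grade power of the dialect, `pi_fun`
# maps a (mu, nu) pair to the dialect's powered hesitancy term.
pi_fun_for <- function(hesitancy, k) {
  switch(hesitancy,
    none = function(mu, nu) 0,
    intuitionistic = function(mu, nu) 1 - mu - nu,
    pythagorean = function(mu, nu) max(0, 1 - mu^2 - nu^2)^(k / 2))
}

oracle_distance <- function(measure, P, Q, power = 2,
                            hesitancy = "pythagorean", variant = "printed") {
  n <- nrow(P)
  k <- power
  pf <- pi_fun_for(hesitancy, k)
  acc <- 0
  for (i in seq_len(n)) {
    mP <- P$mu[i]; nP <- P$nu[i]; mQ <- Q$mu[i]; nQ <- Q$nu[i]
    pP <- pf(mP, nP); pQ <- pf(mQ, nQ)
    a <- abs(mP^k - mQ^k); b <- abs(nP^k - nQ^k); h <- abs(pP - pQ)
    acc <- acc + switch(measure,
      hamming        = a + b + h,
      euclidean      = a^2 + b^2 + h^2,
      norm_hamming   = a + b + h,
      norm_euclidean = a^2 + b^2 + h^2,
      ba_sq1         = (sqrt(mP) - sqrt(mQ))^2 + (sqrt(nP) - sqrt(nQ))^2,
      ba_sq2         = (sqrt(a) + sqrt(b))^2,
      grzegorzewski  = max(a, b),
      yang_chiclana  = max(a, b, h),
      wang_xin       = (a + b) / 4 + max(a, b) / 2,
      jin            = a + b + h + 2 * max(a, b, h),
      song           = {
        pP1 <- pi_fun_for(hesitancy, 1)(mP, nP)
        pQ1 <- pi_fun_for(hesitancy, 1)(mQ, nQ)
        pr <- pP1 * pQ1
        if (pr < 0 && pr >= -1e-9) pr <- 0
        2 * sqrt(mP * mQ) + 2 * sqrt(nP * nQ) + sqrt(pr) +
          sqrt((1 - mP) * (1 - mQ)) + sqrt((1 - nP) * (1 - nQ))
      },
      ren            = a^2 + b^2 + h^2,
      peng           = if (variant == "table") a + b + h
                       else a^2 + b^2 + h^2,
      ejegwa_awolola = abs(mP^k - mQ^k) + abs(mP^k - nP^k) - abs(mQ^k - nQ^k) +
                       abs(mP^k - pP) - abs(mQ^k - pQ),
      sarkar_biswas  = a + b + h + abs(max(mP^k, nQ^k) - max(mQ^k, nP^k)),
      mahanta_panda  = {
        den <- mP^k + mQ^k + nP^k + nQ^k
        if (den == 0) 0 else (a + b) / den
      })
  }
  switch(measure,
    hamming = acc / 2,
    euclidean = sqrt(acc / 2),
    norm_hamming = acc / (2 * n),
    norm_euclidean = sqrt(acc / (2 * n)),
    ba_sq1 = acc / (2 * n),
    ba_sq2 = acc / (4 * n),
    grzegorzewski = acc / n,
    yang_chiclana = acc / n,
    wang_xin = acc / n,
    jin = acc / (4 * n),
    song = 1 - acc / (3 * n),
    ren = sqrt(acc / (2 * n)),
    peng = if (variant == "table") acc / (2 * n) else acc / (4 * n),
    ejegwa_awolola = acc / (4 * n),
    sarkar_biswas = acc / (3 * n),
    mahanta_panda = acc / n)
}

# Naive chordal-family oracles, written term by term from the definitions.
oracle_chordal <- function(P, Q, p) {
  acc <- 0
  for (i in seq_len(nrow(P))) {
    km <- abs(P$mu[i] - Q$mu[i]) / (sqrt(1 + P$mu[i]^2) * sqrt(1 + Q$mu[i]^2))
    kn <- abs(P$nu[i] - Q$nu[i]) / (sqrt(1 + P$nu[i]^2) * sqrt(1 + Q$nu[i]^2))
    acc <- acc + km^p + kn^p
  }
  (acc / (2^(1 - p / 2) * nrow(P)))^(1 / p)
}

oracle_nonarch <- function(P, Q, p, lam) {
  n <- nrow(P)
  acc <- 0
  for (i in seq_len(n)) {
    km <- abs(P$mu[i] - Q$mu[i]) / (max(lam, P$mu[i]) * max(lam, Q$mu[i]))
    kn <- abs(P$nu[i] - Q$nu[i]) / (max(lam, P$nu[i]) * max(lam, Q$nu[i]))
    acc <- acc + (km / (20 * n))^p + (kn / (20 * n))^p
  }
  acc^(1 / p)
}
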