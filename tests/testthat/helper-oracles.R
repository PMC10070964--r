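# Independent brute-force bioclim oracle: enumerates every wrap-around
# quarter explicitly and computes each variable from first principles.
brute_bioclim <- function(tmin, tmax, prec) {
  tavg <- (tmin + tmax) / 2
  qt <- qp <- numeric(12)
  for (m in 1:12) {
    members <- c(m, m %% 12 + 1, (m + 1) %% 12 + 1)
    qt[m] <- mean(tavg[members])
    qp[m] <- sum(prec[members])
  }
  out <- numeric(19)
  out[1] <- mean(tavg)
  out[2] <- mean(tmax - tmin)
  out[5] <- max(tmax); out[6] <- min(tmin); out[7] <- out[5] - out[6]
  out[3] <- if (out[7] > 0) 100 * out[2] / out[7] else NA
  out[4] <- 100 * sd(tavg)
  out[8] <- qt[which.max(qp)]; out[9] <- qt[which.min(qp)]
  out[10] <- qt[which.max(qt)]; out[11] <- qt[which.min(qt)]
  out[12] <- sum(prec); out[13] <- max(prec); out[14] <- min(prec)
  out[15] <- 100 * sd(prec) / (1 + mean(prec))
  out[16] <- qp[which.max(qp)]; out[17] <- qp[which.min(qp)]
  out[18] <- qp[which.max(qt)]; out[19] <- qp[which.min(qt)]
  names(out) <- paste0("BIO", 1:19)
  out
}
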