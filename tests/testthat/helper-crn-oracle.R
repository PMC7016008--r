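# Independent R transcription of the Courtemanche-Ramirez-Nattel (1998)
# human atrial model, integrated with deSolve. Used as the oracle for the
# compiled engine: same published constants, independently written code
# path (plain R, alpha/beta form, stiff solver instead of Rush-Larsen).

crn_oracle_rhs <- function(t, y, p) {
  V <- y[1]; m <- y[2]; h <- y[3]; j <- y[4]
  oa <- y[5]; oi <- y[6]; ua <- y[7]; ui <- y[8]
  xr <- y[9]; xs <- y[10]; d <- y[11]; f <- y[12]; fca <- y[13]
  u <- y[14]; v <- y[15]; w <- y[16]
  Nai <- y[17]; Ki <- y[18]; Cai <- y[19]; Caup <- y[20]; Carel <- y[21]

  R <- 8.3143; Temp <- 310; Fa <- 96.4867; Cm <- 100
  Vi <- 13668; Vup <- 1109.52; Vrel <- 96.48
  Ko <- 5.4; Nao <- 140; Cao <- 1.8
  RTF <- R * Temp / Fa
  ENa <- RTF * log(Nao / Nai)
  EK <- RTF * log(Ko / Ki)
  ECa <- RTF / 2 * log(Cao / Cai)

  fK1 <- p$fac[1]; fNCX <- p$fac[2]; fNa <- p$fac[3]
  fto <- p$fac[4]; fCaL <- p$fac[5]; fKur <- p$fac[6]

  iNa <- fNa * Cm * 7.8 * m^3 * h * j * (V - ENa)
  iK1 <- fK1 * Cm * 0.09 * (V - EK) / (1 + exp(0.07 * (V + 80)))
  ito <- fto * Cm * 0.1652 * oa^3 * oi * (V - EK)
  gKur <- 0.005 + 0.05 / (1 + exp((V - 15) / -13))
  iKur <- fKur * Cm * gKur * ua^3 * ui * (V - EK)
  iKr <- Cm * 0.029411765 * xr * (V - EK) / (1 + exp((V + 15) / 22.4))
  iKs <- Cm * 0.12941176 * xs^2 * (V - EK)
  iCaL <- fCaL * Cm * 0.12375 * d * f * fca * (V - 65)
  sig <- (exp(Nao / 67.3) - 1) / 7
  fNaK <- 1 / (1 + 0.1245 * exp(-0.1 * V / RTF) + 0.0365 * sig * exp(-V / RTF))
  iNaK <- Cm * 0.59933874 * fNaK / (1 + (10 / Nai)^1.5) * (Ko / (Ko + 1.5))
  iNaCa <- fNCX * Cm * 1600 *
    (exp(0.35 * V / RTF) * Nai^3 * Cao -
       exp(-0.65 * V / RTF) * Nao^3 * Cai) /
    ((87.5^3 + Nao^3) * (1.38 + Cao) * (1 + 0.1 * exp(-0.65 * V / RTF)))
  iBNa <- Cm * 0.0006744375 * (V - ENa)
  iBCa <- Cm * 0.001131 * (V - ECa)
  iCaP <- Cm * 0.275 * Cai / (0.0005 + Cai)

  irel <- 30 * u^2 * v * w * (Carel - Cai)
  itr <- (Caup - Carel) / 180
  iup <- 0.005 / (1 + 0.00092 / Cai)
  iupleak <- 0.005 * Caup / 15

  istim <- p$stim(t)

  # gate kinetics
  am <- if (abs(V + 47.13) < 1e-10) 3.2 else
    0.32 * (V + 47.13) / (1 - exp(-0.1 * (V + 47.13)))
  bm <- 0.08 * exp(-V / 11)
  if (V < -40) {
    ah <- 0.135 * exp((V + 80) / -6.8)
    bh <- 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V)
    aj <- (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  } else {
    ah <- 0
    bh <- 1 / (0.13 * (1 + exp((V + 10.66) / -11.1)))
    aj <- 0
    bj <- 0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32)))
  }
  aoa <- 0.65 / (exp((V + 10) / -8.5) + exp((V - 30) / -59))
  boa <- 0.65 / (2.5 + exp((V + 82) / 17))
  oainf <- 1 / (1 + exp((V + 20.47) / -17.54))
  aoi <- 1 / (18.53 + exp((V + 113.7) / 10.95))
  boi <- 1 / (35.56 + exp((V + 1.26) / -7.44))
  oiinf <- 1 / (1 + exp((V + 43.1) / 5.3))
  uainf <- 1 / (1 + exp((V + 30.3) / -9.6))
  aui <- 1 / (21 + exp((V - 185) / -28))
  bui <- exp((V - 158) / 16)
  uiinf <- 1 / (1 + exp((V - 99.45) / 27.48))
  axr <- if (abs(V + 14.1) < 1e-10) 0.0015 else
    0.0003 * (V + 14.1) / (1 - exp((V + 14.1) / -5))
  bxr <- if (abs(V - 3.3328) < 1e-10) 3.7836118e-4 else
    7.3898e-5 * (V - 3.3328) / (exp((V - 3.3328) / 5.1237) - 1)
  xrinf <- 1 / (1 + exp((V + 14.1) / -6.5))
  axs <- if (abs(V - 19.9) < 1e-10) 0.00068 else
    4e-5 * (V - 19.9) / (1 - exp((V - 19.9) / -17))
  bxs <- if (abs(V - 19.9) < 1e-10) 0.000315 else
    3.5e-5 * (V - 19.9) / (exp((V - 19.9) / 9) - 1)
  xsinf <- 1 / sqrt(1 + exp((V - 19.9) / -12.7))
  dinf <- 1 / (1 + exp((V + 10) / -8))
  taud <- if (abs(V + 10) < 1e-10) 4.579 / (1 + exp((V + 10) / -6.24)) else
    (1 - exp((V + 10) / -6.24)) /
      (0.035 * (V + 10) * (1 + exp((V + 10) / -6.24)))
  finf <- 1 / (1 + exp((V + 28) / 6.9))
  tauf <- 9 / (0.0197 * exp(-0.0337^2 * (V + 10)^2) + 0.02)
  fcainf <- 1 / (1 + Cai / 0.00035)
  Fn <- 1e3 * (1e-15 * Vrel * irel - 1e-15 / (2 * Fa) *
                 (0.5 * iCaL - 0.2 * iNaCa))
  uinf <- 1 / (1 + exp(-(Fn - 3.4175e-13) / 1.367e-15))
  vinf <- 1 - 1 / (1 + exp(-(Fn - 6.835e-14) / 1.367e-15))
  tauv <- 1.91 + 2.09 / (1 + exp(-(Fn - 3.4175e-13) / 1.367e-15))
  winf <- 1 - 1 / (1 + exp(-(V - 40) / 17))
  tauw <- if (abs(V - 7.9) < 1e-10) 6 * 0.2 / 1.3 else
    6 * (1 - exp(-(V - 7.9) / 5)) /
      ((1 + 0.3 * exp(-(V - 7.9) / 5)) * (V - 7.9))

  KQ10 <- 3
  dy <- numeric(21)
  dy[1] <- -(iNa + iK1 + ito + iKur + iKr + iKs + iBNa + iBCa + iNaK +
               iCaP + iNaCa + iCaL + istim) / Cm
  dy[2] <- am * (1 - m) - bm * m
  dy[3] <- ah * (1 - h) - bh * h
  dy[4] <- aj * (1 - j) - bj * j
  dy[5] <- (oainf - oa) * (aoa + boa) * KQ10
  dy[6] <- (oiinf - oi) * (aoi + boi) * KQ10
  dy[7] <- (uainf - ua) * (aoa + boa) * KQ10
  dy[8] <- (uiinf - ui) * (aui + bui) * KQ10
  dy[9] <- (xrinf - xr) * (axr + bxr)
  dy[10] <- (xsinf - xs) * (axs + bxs) * 2
  dy[11] <- (dinf - d) / taud
  dy[12] <- (finf - f) / tauf
  dy[13] <- (fcainf - fca) / 2
  dy[14] <- (uinf - u) / 8
  dy[15] <- (vinf - v) / tauv
  dy[16] <- (winf - w) / tauw
  dy[17] <- (-3 * iNaK - 3 * iNaCa - iBNa - iNa) / (Vi * Fa)
  dy[18] <- (2 * iNaK - (iK1 + ito + iKur + iKr + iKs)) / (Vi * Fa)
  B1 <- (2 * iNaCa - (iCaP + iCaL + iBCa)) / (2 * Vi * Fa) +
    (Vup * (iupleak - iup) + irel * Vrel) / Vi
  B2 <- 1 + 0.07 * 0.0005 / (Cai + 0.0005)^2 +
    0.05 * 0.00238 / (Cai + 0.00238)^2
  dy[19] <- B1 / B2
  dy[20] <- iup - iupleak - itr * Vrel / Vup
  dy[21] <- (itr - irel) / (1 + 10 * 0.8 / (Carel + 0.8)^2)
  list(dy)
}

# integrate one paced beat with the oracle; returns times and vm
crn_oracle_beat <- function(scaling = neutral_profile(), duration = 600,
                            stim_amp = -2000, stim_dur = 2, out_dt = 0.5) {
  stim <- function(t) if (t >= 0 && t < stim_dur) stim_amp else 0
  out <- deSolve::lsoda(y = unname(crn_resting_state()),
                        times = seq(0, duration, by = out_dt),
                        func = crn_oracle_rhs,
                        parms = list(fac = as.numeric(scaling), stim = stim),
                        rtol = 1e-8, atol = 1e-8, maxsteps = 50000)
  list(times = out[, 1], vm = out[, 2])
}
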