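# Independent straight-line oracle for the toy crop model: plain R loops
# with the update equations written out by hand, sharing no code with the
# compiled engine. Used to pin down simulate_model() on the full model.

hand_toy_sim <- function(drv) {
  n <- drv$n_days
  sites <- drv$sites
  ns <- length(sites)
  TMIN <- drv$streams$tmin; TMAX <- drv$streams$tmax
  RADN <- drv$streams$radn; RAIN <- drv$streams$rain
  vars <- c("tmean", "tsoil_adj", "s_soiltemp", "dtt", "tt", "lnum",
            "anth", "cum_rain", "evap", "transp", "sw", "dfac", "rue_mod",
            "ctemp_adj", "s_ctemp", "lai", "fint", "biomass", "bio_anth",
            "trans_pot", "grain")
  out <- sapply(vars, function(v) matrix(NA_real_, n, ns),
                simplify = FALSE)
  p_lai <- rep(0, ns); p_tt <- rep(0, ns); p_cum <- rep(0, ns)
  p_sw <- rep(120, ns); p_bio <- rep(0, ns); p_ba <- rep(0, ns)
  p_gr <- rep(0, ns)
  for (d in seq_len(n)) {
    tmin <- TMIN[d, ]; tmax <- TMAX[d, ]; radn <- RADN[d, ]
    rain <- RAIN[d, ]
    tmean <- (tmin + tmax) / 2
    tsoil_adj <- 0.02 * exp(-1.2 * p_lai) * (0.5 * (tmax - tmin) - 5)
    s_soiltemp <- rep(1, ns)
    dtt <- pmax(0, tmean + s_soiltemp * tsoil_adj - 0)
    tt <- p_tt + dtt
    lnum <- pmin(9, tt / 95)
    anth <- ifelse(tt >= (9 + 3) * 95, 1, 0)
    cum_rain <- p_cum + rain
    evap <- 0.25 * (0.35 + 0.65 * exp(-1.5 * p_lai))
    transp <- 0.28 * p_lai * pmax(0, radn) / 10
    sw <- pmax(0, pmin(120, p_sw + rain - evap - transp))
    dfac <- pmin(1, sw / 50)
    rue_mod <- 1 + 0.18 * ((tmax - tmin) - 10) / 4
    ctemp_adj <- 0.18 * (radn - 12) / 8
    s_ctemp <- rep(1, ns)
    lai <- pmax(0, p_lai + 0.006 * dtt * dfac * ifelse(lnum < 9, 1, 0) -
                  0.003 * p_lai * dtt * ifelse(anth > 0.5, 1, 0) *
                  (1 + 2.5 * (1 - dfac)))
    fint <- 1 - exp(-0.6 * lai)
    biomass <- p_bio + 1.3 * rue_mod * (0.5 * radn) * fint *
      (0.35 + 0.65 * dfac)
    bio_anth <- ifelse(anth > 0.5, ifelse(p_ba > 0, p_ba, biomass), 0)
    trans_pot <- 0.25 * bio_anth
    grain <- pmin(pmax(0, p_gr + ifelse(anth > 0.5,
                                        0.7 * dtt * (1 + s_ctemp * ctemp_adj) * fint,
                                        0)),
                  0.6 * biomass + trans_pot)
    for (v in vars) out[[v]][d, ] <- get(v)
    p_lai <- lai; p_tt <- tt; p_cum <- cum_rain; p_sw <- sw
    p_bio <- biomass; p_ba <- bio_anth; p_gr <- grain
  }
  for (v in vars) colnames(out[[v]]) <- sites
  out
}
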