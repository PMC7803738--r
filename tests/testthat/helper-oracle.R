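# Brute-force reference Monte Carlo for the sapphire/tissue/sapphire slab,
# written independently of the package's compiled simulator: plain sampled
# decisions everywhere (sampled specular reflection, sampled interface
# reflections, no ballistic cascade, no forced interactions, no splitting,
# no Russian roulette — just a hard low-weight cutoff whose bias is below
# 1e-6). Propagation is vectorized in lockstep over all photons using R's
# own RNG. Scores diffuse reflectance (top exits within the port, specular
# excluded) and total transmittance (bottom exits within the port), with
# per-photon standard errors.
oracle_forward <- function(mu_a, mu_s, g,
                           d_tissue = 0.3, n_tissue = 1.4,
                           n_window = 1.76, d_window = 1.0,
                           n_ambient = 1.0,
                           beam_radius = 0.95, port_radius = 2.5,
                           lateral_extent = 6.0,
                           n_photons = 1e5, seed = 1) {
  set.seed(seed)
  mua <- c(0, mu_a, 0)
  mus <- c(0, mu_s, 0)
  gv <- c(0, g, 0)
  nl <- c(n_window, n_tissue, n_window)
  zb <- c(0, d_window, d_window + d_tissue, 2 * d_window + d_tissue)
  N <- as.integer(n_photons)

  rr <- beam_radius * sqrt(stats::runif(N))
  th <- 2 * pi * stats::runif(N)
  x <- rr * cos(th); y <- rr * sin(th); z <- numeric(N)
  ux <- numeric(N); uy <- numeric(N); uz <- rep(1, N)
  rsp <- ((n_ambient - n_window) / (n_ambient + n_window))^2
  alive <- stats::runif(N) >= rsp   # sampled order-0 specular reflection
  w <- rep(1, N)
  lay <- rep(1L, N)
  sleft <- numeric(N)
  rd <- numeric(N); tt <- numeric(N)

  hg_draw <- function(gg, n) {
    u <- stats::runif(n)
    if (abs(gg) < 1e-12) return(2 * u - 1)
    t <- (1 - gg^2) / (1 - gg + 2 * gg * u)
    pmin(1, pmax(-1, (1 + gg^2 - t^2) / (2 * gg)))
  }

  it <- 0
  while (any(alive) && it < 5e4) {
    it <- it + 1
    id <- which(alive)
    L <- lay[id]
    mt <- mua[L] + mus[L]
    draw <- sleft[id] <= 0 & mt > 0
    if (any(draw)) sleft[id[draw]] <- -log(1 - stats::runif(sum(draw)))

    uzi <- uz[id]
    db <- rep(Inf, length(id))
    up <- uzi > 1e-12
    dn <- uzi < -1e-12
    db[up] <- (zb[L + 1L][up] - z[id][up]) / uzi[up]
    db[dn] <- (zb[L][dn] - z[id][dn]) / uzi[dn]
    sp <- ifelse(mt > 0, sleft[id] / mt, Inf)

    stuck <- !is.finite(db) & !is.finite(sp)
    if (any(stuck)) alive[id[stuck]] <- FALSE

    # --- interactions -----------------------------------------------------
    ii <- id[!stuck & sp < db]
    if (length(ii) > 0) {
      spi <- sleft[ii] / (mua[lay[ii]] + mus[lay[ii]])
      x[ii] <- x[ii] + ux[ii] * spi
      y[ii] <- y[ii] + uy[ii] * spi
      z[ii] <- z[ii] + uz[ii] * spi
      out <- x[ii]^2 + y[ii]^2 > lateral_extent^2
      alive[ii[out]] <- FALSE
      ii <- ii[!out]
      if (length(ii) > 0) {
        Li <- lay[ii]
        w[ii] <- w[ii] * (mus[Li] / (mua[Li] + mus[Li]))
        ct <- hg_draw(gv[Li][1], length(ii))  # single tissue layer: same g
        st <- sqrt(pmax(0, 1 - ct^2))
        phi <- 2 * pi * stats::runif(length(ii))
        cp <- cos(phi); sp2 <- sin(phi)
        uzi <- uz[ii]; uxi <- ux[ii]; uyi <- uy[ii]
        near_pole <- abs(uzi) > 0.99999
        den <- sqrt(pmax(1e-30, 1 - uzi^2))
        nx <- ifelse(near_pole, st * cp,
                     st * (uxi * uzi * cp - uyi * sp2) / den + uxi * ct)
        ny <- ifelse(near_pole, st * sp2,
                     st * (uyi * uzi * cp + uxi * sp2) / den + uyi * ct)
        nz <- ifelse(near_pole, sign(uzi) * ct,
                     -den * st * cp + uzi * ct)
        nrm <- sqrt(nx^2 + ny^2 + nz^2)
        ux[ii] <- nx / nrm; uy[ii] <- ny / nrm; uz[ii] <- nz / nrm
        sleft[ii] <- 0
        dead <- w[ii] < 1e-7    # hard cutoff (bias < 1e-6, documented)
        alive[ii[dead]] <- FALSE
      }
    }

    # --- boundary hits ----------------------------------------------------
    ib <- id[!stuck & sp >= db & is.finite(db)]
    if (length(ib) > 0) {
      Lb <- lay[ib]
      mtb <- mua[Lb] + mus[Lb]
      dbb <- ifelse(uz[ib] > 0, (zb[Lb + 1L] - z[ib]) / uz[ib],
                    (zb[Lb] - z[ib]) / uz[ib])
      x[ib] <- x[ib] + ux[ib] * dbb
      y[ib] <- y[ib] + uy[ib] * dbb
      z[ib] <- ifelse(uz[ib] > 0, zb[Lb + 1L], zb[Lb])
      sleft[ib] <- sleft[ib] - pmax(dbb, 0) * mtb
      out <- x[ib]^2 + y[ib]^2 > lateral_extent^2
      alive[ib[out]] <- FALSE
      ib <- ib[!out]
      if (length(ib) > 0) {
        Lb <- lay[ib]
        down <- uz[ib] > 0
        n1 <- nl[Lb]
        n2 <- ifelse(down,
                     ifelse(Lb == 3L, n_ambient, nl[pmin(Lb + 1L, 3L)]),
                     ifelse(Lb == 1L, n_ambient, nl[pmax(Lb - 1L, 1L)]))
        ci <- abs(uz[ib])
        st2 <- (n1 / n2)^2 * (1 - ci^2)
        tir <- st2 >= 1
        ctr <- sqrt(pmax(0, 1 - st2))
        rs <- (n1 * ci - n2 * ctr) / (n1 * ci + n2 * ctr)
        rp <- (n1 * ctr - n2 * ci) / (n1 * ctr + n2 * ci)
        R <- ifelse(tir, 1, 0.5 * (rs^2 + rp^2))
        refl <- stats::runif(length(ib)) < R
        # reflections
        uz[ib[refl]] <- -uz[ib[refl]]
        # transmissions
        tr <- ib[!refl]
        if (length(tr) > 0) {
          k <- !refl
          ratio <- (n1 / n2)[k]
          ux[tr] <- ux[tr] * ratio
          uy[tr] <- uy[tr] * ratio
          uz[tr] <- ifelse(down[k], ctr[k], -ctr[k])
          Ltr <- lay[tr]
          exit_bot <- down[k] & Ltr == 3L
          exit_top <- !down[k] & Ltr == 1L
          inport <- x[tr]^2 + y[tr]^2 <= port_radius^2
          bb <- tr[exit_bot]
          tt[bb[inport[exit_bot]]] <- w[bb[inport[exit_bot]]]
          alive[bb] <- FALSE
          tp <- tr[exit_top]
          rd[tp[inport[exit_top]]] <- w[tp[inport[exit_top]]]
          alive[tp] <- FALSE
          inner <- tr[!exit_bot & !exit_top]
          lay[inner] <- lay[inner] + ifelse(down[k][!exit_bot & !exit_top],
                                            1L, -1L)
        }
      }
    }
  }

  se <- function(v) sqrt(max(0, mean(v^2) - mean(v)^2) / N)
  list(Rd = sum(rd) / N, Tt = sum(tt) / N, se_Rd = se(rd), se_Tt = se(tt))
}
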