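# Vectorised metric + analytic-gradient engine.
#
# A is the ground-truth matrix, B the predicted matrix (n x 4, columns
# x, y, w, h); gradients are taken w.r.t. B's four parameters.  min/max
# kinks (shared corner coordinates) use the symmetric subgradient (ties
# weighted 1/2), which coincides with the central finite difference and
# makes the gradient exactly zero for identical boxes.
#
# `fixed` pins quantities that are treated as constants during
# differentiation: $ciouAlpha (CIoU trade-off), $alpha / $scale (S-MPDIoU
# baseline angle and scale factor).  The S-MPDIoU branch selection and the
# scale factor never receive gradient; the baseline itself (through the
# center offsets) does.

.metricGrad <- function(name, A, B, W = NA_real_, H = NA_real_,
                        scaleVal = NA_real_, fixed = list(),
                        wantGrad = TRUE) {
  n <- nrow(B)
  dimnames(A) <- NULL; dimnames(B) <- NULL
  xa <- A[, 1]; ya <- A[, 2]; wa <- A[, 3]; ha <- A[, 4]
  xb <- B[, 1]; yb <- B[, 2]; wb <- B[, 3]; hb <- B[, 4]

  la <- xa - wa / 2; ra <- xa + wa / 2; ta <- ya - ha / 2; ba <- ya + ha / 2
  lb <- xb - wb / 2; rb <- xb + wb / 2; tb <- yb - hb / 2; bb <- yb + hb / 2

  iw <- pmin(ra, rb) - pmax(la, lb); iw[iw < 0] <- 0
  ih <- pmin(ba, bb) - pmax(ta, tb); ih[ih < 0] <- 0
  inter <- iw * ih
  union <- wa * ha + wb * hb - inter
  iou <- inter / union

  cw <- pmax(ra, rb) - pmin(la, lb)
  ch <- pmax(ba, bb) - pmin(ta, tb)

  g <- NULL
  if (wantGrad) {
    tie <- function(lt, eq) lt + 0.5 * eq
    i_rmin <- tie(rb < ra, rb == ra); i_lmax <- tie(lb > la, lb == la)
    i_bmin <- tie(bb < ba, bb == ba); i_tmax <- tie(tb > ta, tb == ta)
    ovx <- as.numeric(iw > 0); ovy <- as.numeric(ih > 0)
    diw_dx <- ovx * (i_rmin - i_lmax); diw_dw <- ovx * 0.5 * (i_rmin + i_lmax)
    dih_dy <- ovy * (i_bmin - i_tmax); dih_dh <- ovy * 0.5 * (i_bmin + i_tmax)

    dI <- cbind(ih * diw_dx, iw * dih_dy, ih * diw_dw, iw * dih_dh)
    dU <- cbind(-dI[, 1], -dI[, 2], hb - dI[, 3], wb - dI[, 4])
    dIoU <- (dI * union - inter * dU) / union^2

    e_rmax <- tie(rb > ra, rb == ra); e_lmin <- tie(lb < la, lb == la)
    e_bmax <- tie(bb > ba, bb == ba); e_tmin <- tie(tb < ta, tb == ta)
    dcw <- cbind(e_rmax - e_lmin, 0, 0.5 * (e_rmax + e_lmin), 0)
    dch <- cbind(0, e_bmax - e_tmin, 0, 0.5 * (e_bmax + e_tmin))
    g <- list(dIoU = dIoU, dU = dU, dcw = dcw, dch = dch)
  }

  zero4 <- function() matrix(0, n, 4)

  out <- switch(name,
    iou = list(metric = iou, grad = if (wantGrad) g$dIoU),

    giou = {
      # IoU - (Ac - U)/Ac  ==  IoU - 1 + U/Ac
      Ac <- cw * ch
      m <- iou - 1 + union / Ac
      gr <- NULL
      if (wantGrad) {
        dAc <- ch * g$dcw + cw * g$dch
        gr <- g$dIoU + (g$dU * Ac - union * dAc) / Ac^2
      }
      list(metric = m, grad = gr)
    },

    diou = , ciou = , eiou = {
      rho2 <- (xb - xa)^2 + (yb - ya)^2
      c2 <- cw^2 + ch^2
      dm <- iou - rho2 / c2
      gr <- NULL
      if (wantGrad) {
        drho2 <- cbind(2 * (xb - xa), 2 * (yb - ya), 0, 0)
        dc2 <- 2 * cw * g$dcw + 2 * ch * g$dch
        gr <- g$dIoU - (drho2 * c2 - rho2 * dc2) / c2^2
      }
      if (name == "diou") {
        list(metric = dm, grad = gr)
      } else if (name == "ciou") {
        datan <- atan(wa / ha) - atan(wb / hb)
        v <- (4 / pi^2) * datan^2
        alpha <- if (!is.null(fixed$ciouAlpha)) fixed$ciouAlpha
                 else ifelse(v == 0, 0, v / (1 - iou + v))  # frozen during differentiation
        m <- dm - alpha * v
        if (wantGrad) {
          s2 <- wb^2 + hb^2
          dv <- cbind(0, 0, -2 * (4 / pi^2) * datan * hb / s2,
                             2 * (4 / pi^2) * datan * wb / s2)
          gr <- gr - alpha * dv
        }
        list(metric = m, grad = gr)
      } else {
        dw <- wb - wa; dh <- hb - ha
        m <- dm - dw^2 / cw^2 - dh^2 / ch^2
        if (wantGrad) {
          dtw <- cbind(-2 * dw^2 * g$dcw[, 1] / cw^3, 0,
                       2 * dw / cw^2 - 2 * dw^2 * g$dcw[, 3] / cw^3, 0)
          dth <- cbind(0, -2 * dh^2 * g$dch[, 2] / ch^3, 0,
                       2 * dh / ch^2 - 2 * dh^2 * g$dch[, 4] / ch^3)
          gr <- gr - dtw - dth
        }
        list(metric = m, grad = gr)
      }
    },

    siou = {
      dx <- xb - xa; dy <- yb - ya
      adx <- abs(dx); ady <- abs(dy)
      sig2 <- dx^2 + dy^2
      deg <- sig2 == 0
      lam <- ifelse(deg, 0, 2 * adx * ady / sig2)   # sin(2*angle)
      gam <- 2 - lam
      rx <- (dx / cw)^2; ry <- (dy / ch)^2
      ex <- exp(-gam * rx); ey <- exp(-gam * ry)
      Del <- (1 - ex) + (1 - ey)
      ww <- abs(wb - wa) / pmax(wb, wa)
      hh <- abs(hb - ha) / pmax(hb, ha)
      eww <- 1 - exp(-ww); ehh <- 1 - exp(-hh)
      Ome <- eww^4 + ehh^4
      m <- iou - (Del + Ome) / 2
      gr <- NULL
      if (wantGrad) {
        sgx <- sign(dx); sgy <- sign(dy)
        s4 <- ifelse(deg, 1, sig2^2)
        dlam_dx <- ifelse(deg, 0, sgx * 2 * ady * (ady^2 - adx^2) / s4)
        dlam_dy <- ifelse(deg, 0, sgy * 2 * adx * (adx^2 - ady^2) / s4)
        dgam <- cbind(-dlam_dx, -dlam_dy, 0, 0)
        drx <- cbind(2 * dx / cw^2 - 2 * dx^2 * g$dcw[, 1] / cw^3, 0,
                     -2 * dx^2 * g$dcw[, 3] / cw^3, 0)
        dry <- cbind(0, 2 * dy / ch^2 - 2 * dy^2 * g$dch[, 2] / ch^3, 0,
                     -2 * dy^2 * g$dch[, 4] / ch^3)
        dDel <- ex * (gam * drx + rx * dgam) + ey * (gam * dry + ry * dgam)
        mxw <- pmax(wb, wa); sgw <- sign(wb - wa); topw <- as.numeric(wb > wa)
        dww_dwb <- (sgw * mxw - abs(wb - wa) * topw) / mxw^2
        mxh <- pmax(hb, ha); sgh <- sign(hb - ha); toph <- as.numeric(hb > ha)
        dhh_dhb <- (sgh * mxh - abs(hb - ha) * toph) / mxh^2
        dOme <- cbind(0, 0, 4 * eww^3 * exp(-ww) * dww_dwb,
                            4 * ehh^3 * exp(-hh) * dhh_dhb)
        gr <- g$dIoU - (dDel + dOme) / 2
      }
      list(metric = m, grad = gr)
    },

    mpdiou = {
      diag2 <- W^2 + H^2
      d1s <- (lb - la)^2 + (tb - ta)^2
      d2s <- (rb - ra)^2 + (bb - ba)^2
      m <- iou - (d1s + d2s) / diag2
      gr <- NULL
      if (wantGrad) {
        dD <- cbind(2 * (lb - la) + 2 * (rb - ra),
                    2 * (tb - ta) + 2 * (bb - ba),
                    -(lb - la) + (rb - ra),
                    -(tb - ta) + (bb - ba))
        gr <- g$dIoU - dD / diag2
      }
      list(metric = m, grad = gr)
    },

    smpdiou = {
      s <- if (!is.null(fixed$scale)) fixed$scale else scaleVal
      Cw <- abs(xb - xa); Ch <- abs(yb - ya)
      if (!is.null(fixed$alpha)) {
        a0 <- fixed$alpha
        C2 <- rep(if (a0 < pi / 4) W^2 * (1 + tan(a0)^2)
                  else H^2 * (1 + 1 / tan(a0)^2), n)
        dC2 <- if (wantGrad) zero4()
      } else {
        deg <- Cw == 0 & Ch == 0
        br2 <- !deg & Ch >= Cw          # angle >= pi/4 (boundary included)
        br1 <- !deg & !br2
        C2 <- numeric(n)
        C2[deg] <- W^2 + H^2
        C2[br1] <- W^2 * (1 + (Ch[br1] / Cw[br1])^2)
        C2[br2] <- H^2 * (1 + (Cw[br2] / Ch[br2])^2)
        if (wantGrad) {
          sgx <- sign(xb - xa); sgy <- sign(yb - ya)
          dC2x <- numeric(n); dC2y <- numeric(n)
          dC2x[br1] <- -2 * W^2 * Ch[br1]^2 * sgx[br1] / Cw[br1]^3
          dC2y[br1] <-  2 * W^2 * Ch[br1] * sgy[br1] / Cw[br1]^2
          dC2x[br2] <-  2 * H^2 * Cw[br2] * sgx[br2] / Ch[br2]^2
          dC2y[br2] <- -2 * H^2 * Cw[br2]^2 * sgy[br2] / Ch[br2]^3
          dC2 <- cbind(dC2x, dC2y, 0, 0)
        }
      }
      d1s <- (lb - la)^2 + (tb - ta)^2
      d2s <- (rb - ra)^2 + (bb - ba)^2
      Dsum <- d1s + d2s
      m <- iou - s * Dsum / C2
      gr <- NULL
      if (wantGrad) {
        dD <- cbind(2 * (lb - la) + 2 * (rb - ra),
                    2 * (tb - ta) + 2 * (bb - ba),
                    -(lb - la) + (rb - ra),
                    -(tb - ta) + (bb - ba))
        gr <- g$dIoU - s * (dD / C2 - Dsum * dC2 / C2^2)
      }
      list(metric = m, grad = gr)
    },

    stop("unknown loss name: ", name)
  )
  if (!wantGrad) out["grad"] <- list(NULL)
  out
}

# resolve a LossSpec into the engine arguments
.specArgs <- function(spec) {
  geo <- spec@geometry
  if (is(geo, "FeatureMapGeometry"))
    list(W = geo@W, H = geo@H,
         scaleVal = if (spec@name == "smpdiou") scaleFactor(geo) else NA_real_)
  else
    list(W = NA_real_, H = NA_real_, scaleVal = NA_real_)
}
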