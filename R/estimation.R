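# ---- nonlinear mixed-effects estimation (Laplace) -------------------------
#
# The marginal likelihood is approximated per subject by the Laplace method:
#   -log L_i ~= l_i(eta_hat) + 0.5 log det H_i - (d/2) log(2pi)
# where l_i is the joint negative log density (Gaussian residuals under the
# combined error model plus the N(0, Omega) prior on eta) and H_i its
# Hessian at the conditional mode. The inner mode search runs simultaneously
# for all subjects of a design group (their problems are separable, so a
# single vectorized evaluation yields every subject's objective and
# finite-difference derivatives), which keeps the nested optimization fast
# enough for simulation-re-estimation studies in plain R.
#
# Fitting is sequential (IPP): the inhibitor models are fitted to their own
# plasma data first; the biomarker model is then fitted conditional on each
# subject's empirical-Bayes inhibitor concentration profile.

# Vectorized damped-Newton minimizer for separable per-subject objectives.
# f maps a d x n matrix of etas to an n-vector of objective values. The
# per-subject problems can be multimodal (absorption-window kinks), so the
# mode search restarts unconverged subjects from deterministic alternative
# starts and keeps the best mode found per subject.
.vnewton_core <- function(f, eta, val, maxit, gtol, h) {
  d <- nrow(eta); n <- ncol(eta)
  gnorm <- rep(Inf, n)
  for (it in seq_len(maxit)) {
    g <- matrix(0, d, n)
    H <- array(0, c(d, d, n))
    fp <- fm <- vector("list", d)
    for (j in seq_len(d)) {
      ep <- eta; ep[j, ] <- ep[j, ] + h
      em <- eta; em[j, ] <- em[j, ] - h
      fp[[j]] <- f(ep); fm[[j]] <- f(em)
      g[j, ] <- (fp[[j]] - fm[[j]]) / (2 * h)
      H[j, j, ] <- (fp[[j]] - 2 * val + fm[[j]]) / h^2
    }
    if (d > 1) {
      for (j in seq_len(d - 1)) for (k in (j + 1):d) {
        ejk <- eta; ejk[j, ] <- ejk[j, ] + h; ejk[k, ] <- ejk[k, ] + h
        fjk <- f(ejk)
        H[j, k, ] <- H[k, j, ] <- (fjk - fp[[j]] - fp[[k]] + val) / h^2
      }
    }
    gnorm <- apply(abs(g), 2, max)
    if (all(gnorm < gtol)) break
    step <- matrix(0, d, n)
    for (i in seq_len(n)) {
      st <- -solve(.make_pd(H[, , i]), g[, i])
      cap <- max(abs(st))
      if (cap > 2) st <- st * (2 / cap)   # trust-region style cap
      step[, i] <- st
    }
    lam <- rep(1, n)
    accepted <- rep(FALSE, n)
    for (ls in 1:10) {
      todo <- !accepted & gnorm >= gtol
      if (!any(todo)) break
      cand <- eta
      cand[, todo] <- eta[, todo, drop = FALSE] +
        step[, todo, drop = FALSE] * matrix(lam[todo], d, sum(todo), byrow = TRUE)
      vc <- f(cand)
      better <- todo & is.finite(vc) & vc < val - 1e-12
      if (any(better)) {
        eta[, better] <- cand[, better]
        val[better] <- vc[better]
        accepted[better] <- TRUE
      }
      lam <- lam / 2
    }
    if (!any(accepted)) break
  }
  list(eta = eta, val = val, gnorm = gnorm)
}

.vnewton <- function(f, eta, maxit = 30, gtol = 1e-3, h = 1e-4) {
  d <- nrow(eta); n <- ncol(eta)
  run <- .vnewton_core(f, eta, f(eta), maxit, gtol, h)
  # restart subjects that did not converge (kink modes, bad starts) from
  # deterministic alternatives; keep the best value per subject
  if (any(run$gnorm >= 10 * gtol)) {
    for (start in list(matrix(0, d, n), matrix(0.5, d, n))) {
      alt <- start
      alt[, run$gnorm < 10 * gtol] <- run$eta[, run$gnorm < 10 * gtol]
      r2 <- .vnewton_core(f, alt, f(alt), maxit, gtol, h)
      swap <- r2$val < run$val - 1e-10
      if (any(swap)) {
        run$eta[, swap] <- r2$eta[, swap]
        run$val[swap] <- r2$val[swap]
        run$gnorm[swap] <- r2$gnorm[swap]
      }
    }
  }
  eta <- run$eta; val <- run$val
  # refresh curvature at the final point for the Laplace determinant
  H <- array(0, c(d, d, n))
  fp <- fm <- vector("list", d)
  for (j in seq_len(d)) {
    ep <- eta; ep[j, ] <- ep[j, ] + h
    em <- eta; em[j, ] <- em[j, ] - h
    fp[[j]] <- f(ep); fm[[j]] <- f(em)
    H[j, j, ] <- (fp[[j]] - 2 * val + fm[[j]]) / h^2
  }
  if (d > 1) {
    for (j in seq_len(d - 1)) for (k in (j + 1):d) {
      ejk <- eta; ejk[j, ] <- ejk[j, ] + h; ejk[k, ] <- ejk[k, ] + h
      fjk <- f(ejk)
      H[j, k, ] <- H[k, j, ] <- (fjk - fp[[j]] - fp[[k]] + val) / h^2
    }
  }
  logdet <- numeric(n)
  for (i in seq_len(n))
    logdet[i] <- 2 * sum(log(diag(chol(.make_pd(H[, , i])))))
  list(eta = eta, val = val, H = H, logdet = logdet, gnorm = run$gnorm)
}

.make_pd <- function(M, max_tries = 8) {
  eps <- 1e-8 * max(1, abs(diag(M)))
  for (i in seq_len(max_tries)) {
    ok <- tryCatch({ chol(M); TRUE }, error = function(e) FALSE)
    if (ok) return(M)
    M <- M + diag(eps, nrow(M))
    eps <- eps * 10
  }
  diag(pmax(diag(M), 1e-6), nrow(M))
}

# Gaussian residual negative log likelihood, summed over columns.
.res_nll <- function(Y, P, prop, add) {
  v <- .res_var(P, prop, add)
  0.5 * colSums(log(2 * pi * v) + (Y - P)^2 / v)
}

.eta_prior_nll <- function(eta, omega) {
  0.5 * colSums(eta^2 / omega^2) + sum(log(omega)) +
    0.5 * length(omega) * log(2 * pi)
}

# ---- dataset parsing ------------------------------------------------------

# datasets: a records data frame or list thereof. Returns a list of subject
# entries with unique keys and per-occasion data.
.parse_subjects <- function(datasets) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  subjects <- list()
  for (si in seq_along(datasets)) {
    d <- validate_dataset(datasets[[si]])
    for (id in unique(d$ID)) {
      dsub <- d[d$ID == id, , drop = FALSE]
      occs <- list()
      for (oc in sort(unique(dsub$OCC))) {
        o <- dsub[dsub$OCC == oc, , drop = FALSE]
        doses <- o[o$EVID == 1, , drop = FALSE]
        obs <- o[o$EVID == 0, , drop = FALSE]
        occs[[as.character(oc)]] <- list(
          occ = oc,
          rif_doses = doses[doses$DRUG == "RIF", c("TIME", "AMT")],
          prob_doses = doses[doses$DRUG == "PROB", c("TIME", "AMT")],
          bm = obs[obs$DVID == 1, c("TIME", "DV")],
          ur = obs[obs$DVID == 2, c("USTART", "TIME", "DV")],
          rif = obs[obs$DVID == 3, c("TIME", "DV")],
          prob = obs[obs$DVID == 4, c("TIME", "DV")])
      }
      sig <- paste(vapply(occs, function(o) paste(
        "R", paste(round(o$rif_doses$TIME, 4), o$rif_doses$AMT, collapse = ";"),
        "P", paste(round(o$prob_doses$TIME, 4), o$prob_doses$AMT, collapse = ";"),
        "b", paste(round(o$bm$TIME, 4), collapse = ";"),
        "u", paste(round(o$ur$USTART, 4), round(o$ur$TIME, 4), collapse = ";"),
        "i", paste(round(c(o$rif$TIME, o$prob$TIME), 4), collapse = ";")),
        character(1)), collapse = "|")
      subjects[[paste0("ds", si, ":", id)]] <-
        list(key = paste0("ds", si, ":", id), dataset = si, id = id,
             occasions = occs, signature = sig)
    }
  }
  subjects
}

.group_subjects <- function(subjects) {
  sigs <- vapply(subjects, `[[`, character(1), "signature")
  split(subjects, factor(sigs, levels = unique(sigs)))
}

# ---- stage 1: inhibitor model fits ---------------------------------------

# Build per-group inhibitor observation matrices. drug: "rif" or "prob".
.inh_groups <- function(groups, drug) {
  out <- list()
  for (g in groups) {
    first <- g[[1]]
    for (oc in names(first$occasions)) {
      o <- first$occasions[[oc]]
      obs <- o[[drug]]
      if (!nrow(obs)) next
      doses <- if (drug == "rif") o$rif_doses else o$prob_doses
      Y <- vapply(g, function(s) s$occasions[[oc]][[drug]]$DV,
                  numeric(nrow(obs)))
      Y <- matrix(Y, nrow = nrow(obs))
      out[[length(out) + 1L]] <- list(
        keys = vapply(g, `[[`, character(1), "key"),
        times = obs$TIME, Y = Y,
        dose_times = doses$TIME, dose_amts = doses$AMT)
    }
  }
  out
}

.fit_rifampicin <- function(groups, pop, ctrl) {
  res <- pop$residual$rifampicin_plasma
  MW <- pop$constants[["MW_RIF"]]
  init <- log(c(pop$fixed[["Tlag_RIF"]], pop$fixed[["Tk0_RIF"]],
                pop$fixed[["V_RIF"]], pop$fixed[["CL_RIF"]],
                res$prop, pop$iiv[["Tlag_RIF"]], pop$iiv[["Tk0_RIF"]],
                pop$iiv[["CL_RIF"]]))
  names(init) <- c("Tlag_RIF", "Tk0_RIF", "V_RIF", "CL_RIF",
                   "sigma_prop_RIF", "om_Tlag_RIF", "om_Tk0_RIF", "om_CL_RIF")
  init <- init + ctrl$init_shift[seq_along(init) %% 2 + 1]
  warm <- new.env()
  obj <- function(tp, inner_maxit = ctrl$inner_maxit, gtol = ctrl$inner_gtol) {
    th <- exp(tp)
    total <- 0
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      ns <- ncol(g$Y)
      f <- function(eta) {
        P <- .rif_conc_mat(g$times, g$dose_times, g$dose_amts,
                           th[1] * exp(eta[1, ]), th[2] * exp(eta[2, ]),
                           rep(th[3], ns), th[4] * exp(eta[3, ]), MW)
        .res_nll(g$Y, P, th[5], res$add) + .eta_prior_nll(eta, th[6:8])
      }
      eta0 <- if (!is.null(warm[[as.character(gi)]])) warm[[as.character(gi)]] else matrix(0, 3, ns)
      vn <- .vnewton(f, eta0, maxit = inner_maxit, gtol = gtol)
      warm[[as.character(gi)]] <- vn$eta
      total <- total + sum(vn$val + 0.5 * vn$logdet - 1.5 * log(2 * pi))
    }
    total
  }
  opt <- stats::nlminb(init, obj, control = list(iter.max = ctrl$iter.max,
                                                 eval.max = ctrl$eval.max,
                                                 rel.tol = ctrl$rel.tol))
  obj(opt$par)   # refresh conditional modes at the optimum
  ebes <- list()
  for (gi in seq_along(groups)) {
    eta <- warm[[as.character(gi)]]
    th <- exp(opt$par)
    for (i in seq_along(groups[[gi]]$keys))
      ebes[[groups[[gi]]$keys[i]]] <- c(
        Tlag_RIF = th[[1]] * exp(eta[1, i]),
        Tk0_RIF = th[[2]] * exp(eta[2, i]),
        V_RIF = th[[3]], CL_RIF = th[[4]] * exp(eta[3, i]))
  }
  list(par = exp(opt$par), objective = opt$objective, obj_fun = obj,
       tpar = opt$par, convergence = opt$convergence, ebes = ebes,
       message = opt$message, d_eta = 3)
}

.fit_probenecid <- function(groups, pop, ctrl) {
  res <- pop$residual$probenecid_plasma
  MW <- pop$constants[["MW_PROB"]]
  init <- log(c(pop$fixed[["ka_PROB"]], pop$fixed[["V_PROB"]],
                pop$fixed[["CL_PROB"]], res$prop,
                pop$iiv[["V_PROB"]], pop$iiv[["CL_PROB"]]))
  names(init) <- c("ka_PROB", "V_PROB", "CL_PROB", "sigma_prop_PROB",
                   "om_V_PROB", "om_CL_PROB")
  init <- init + ctrl$init_shift[seq_along(init) %% 2 + 1]
  warm <- new.env()
  obj <- function(tp, inner_maxit = ctrl$inner_maxit, gtol = ctrl$inner_gtol) {
    th <- exp(tp)
    total <- 0
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      ns <- ncol(g$Y)
      f <- function(eta) {
        P <- .prob_conc_mat(g$times, g$dose_times, g$dose_amts,
                            rep(th[1], ns), th[2] * exp(eta[1, ]),
                            th[3] * exp(eta[2, ]), MW)
        .res_nll(g$Y, P, th[4], res$add) + .eta_prior_nll(eta, th[5:6])
      }
      eta0 <- if (!is.null(warm[[as.character(gi)]])) warm[[as.character(gi)]] else matrix(0, 2, ns)
      vn <- .vnewton(f, eta0, maxit = inner_maxit, gtol = gtol)
      warm[[as.character(gi)]] <- vn$eta
      total <- total + sum(vn$val + 0.5 * vn$logdet - 1 * log(2 * pi))
    }
    total
  }
  opt <- stats::nlminb(init, obj, control = list(iter.max = ctrl$iter.max,
                                                 eval.max = ctrl$eval.max,
                                                 rel.tol = ctrl$rel.tol))
  obj(opt$par)   # refresh conditional modes at the optimum
  ebes <- list()
  for (gi in seq_along(groups)) {
    eta <- warm[[as.character(gi)]]
    th <- exp(opt$par)
    for (i in seq_along(groups[[gi]]$keys))
      ebes[[groups[[gi]]$keys[i]]] <- c(
        ka_PROB = th[[1]], V_PROB = th[[2]] * exp(eta[1, i]),
        CL_PROB = th[[3]] * exp(eta[2, i]))
  }
  list(par = exp(opt$par), objective = opt$objective, obj_fun = obj,
       tpar = opt$par, convergence = opt$convergence, ebes = ebes,
       message = opt$message, d_eta = 2)
}

# ---- stage 2: biomarker model fit ----------------------------------------

# Precompute per-group occasion contexts conditional on individual inhibitor
# profiles (fixed during the biomarker stage).
.bm_contexts <- function(groups, pop, inh_ebes, grid_step) {
  ctxs <- list()
  for (g in groups) {
    first <- g[[1]]
    keys <- vapply(g, `[[`, character(1), "key")
    ns <- length(keys)
    occs <- list()
    for (oc in names(first$occasions)) {
      o1 <- first$occasions[[oc]]
      if (!nrow(o1$bm) && !nrow(o1$ur)) next
      has_rif <- nrow(o1$rif_doses) > 0
      has_prob <- nrow(o1$prob_doses) > 0
      Ybm <- matrix(vapply(g, function(s) s$occasions[[oc]]$bm$DV,
                           numeric(nrow(o1$bm))), nrow = nrow(o1$bm))
      Yur <- matrix(vapply(g, function(s) s$occasions[[oc]]$ur$DV,
                           numeric(nrow(o1$ur))), nrow = nrow(o1$ur))
      if (!has_rif && !has_prob) {
        occs[[oc]] <- list(type = "const", Ybm = Ybm, Yur = Yur,
                           n_bm = nrow(o1$bm),
                           ur_w = if (nrow(o1$ur)) o1$ur$TIME - o1$ur$USTART else numeric(0))
        next
      }
      dur <- max(o1$bm$TIME, o1$ur$TIME, 0)
      rd <- if (has_rif) dose_events("rifampicin", o1$rif_doses$TIME, o1$rif_doses$AMT) else NULL
      pd <- if (has_prob) dose_events("probenecid", o1$prob_doses$TIME, o1$prob_doses$AMT) else NULL
      grid <- .make_grid(dur, grid_step, rd, pd, pop$fixed[["Tlag_RIF"]],
                         pop$fixed[["Tk0_RIF"]],
                         extra = c(o1$bm$TIME, o1$ur$USTART, o1$ur$TIME))
      getp <- function(key, nm, fallback)
        if (!is.null(inh_ebes[[key]]) && nm %in% names(inh_ebes[[key]]))
          inh_ebes[[key]][[nm]] else fallback
      Curif <- if (has_rif) {
        cs <- pop$constants
        cs[["fu_RIF"]] * .rif_conc_mat(
          grid, rd$time, rd$amount,
          vapply(keys, getp, numeric(1), nm = "Tlag_RIF", fallback = pop$fixed[["Tlag_RIF"]]),
          vapply(keys, getp, numeric(1), nm = "Tk0_RIF", fallback = pop$fixed[["Tk0_RIF"]]),
          vapply(keys, getp, numeric(1), nm = "V_RIF", fallback = pop$fixed[["V_RIF"]]),
          vapply(keys, getp, numeric(1), nm = "CL_RIF", fallback = pop$fixed[["CL_RIF"]]),
          cs[["MW_RIF"]])
      } else matrix(0, length(grid), ns)
      Cuprob <- if (has_prob) {
        cs <- pop$constants
        cs[["fu_PROB"]] * .prob_conc_mat(
          grid, pd$time, pd$amount,
          vapply(keys, getp, numeric(1), nm = "ka_PROB", fallback = pop$fixed[["ka_PROB"]]),
          vapply(keys, getp, numeric(1), nm = "V_PROB", fallback = pop$fixed[["V_PROB"]]),
          vapply(keys, getp, numeric(1), nm = "CL_PROB", fallback = pop$fixed[["CL_PROB"]]),
          cs[["MW_PROB"]])
      } else matrix(0, length(grid), ns)
      occs[[oc]] <- list(
        type = "dyn", grid = grid, Curif = Curif, Cuprob = Cuprob,
        prob_occ = has_prob, Ybm = Ybm, Yur = Yur,
        bm_idx = match(o1$bm$TIME, grid),
        ur_i0 = match(o1$ur$USTART, grid), ur_i1 = match(o1$ur$TIME, grid))
    }
    ctxs[[length(ctxs) + 1L]] <- list(keys = keys, ns = ns, occs = occs)
  }
  ctxs
}

# Per-subject joint nll for one biomarker-stage group at structural values
# th (named list/vector) and etas (3 x ns: ksyn, CLR, Ki_u_OAT3).
.bm_group_nll <- function(ctx, eta, th, Vc, sig_pl, sig_ur, omega) {
  ksyn <- th[["ksyn"]] * exp(eta[1, ])
  CLR <- th[["CLR"]] * exp(eta[2, ])
  Ki3 <- th[["Ki_u_OAT3"]] * exp(eta[3, ])
  CLh <- th[["CLh"]]
  C0 <- ksyn / (CLh + CLR)
  ns <- ctx$ns
  nll <- numeric(ns)
  for (o in ctx$occs) {
    if (o$type == "const") {
      if (nrow(o$Ybm)) {
        P <- matrix(C0, nrow(o$Ybm), ns, byrow = TRUE)
        nll <- nll + .res_nll(o$Ybm, P, sig_pl, 0)
      }
      if (nrow(o$Yur)) {
        P <- outer(o$ur_w, C0 * CLR)
        nll <- nll + .res_nll(o$Yur, P, sig_ur, 0)
      }
    } else {
      mh <- 1 / ((if (o$prob_occ) th[["X"]] else 1) *
                   (1 + o$Curif / th[["Ki_u_OATP1B3"]]))
      mr <- 1 / (1 + sweep(o$Cuprob, 2, Ki3, "/"))
      clh <- CLh * mh
      clr <- sweep(mr, 2, CLR, "*")
      kel <- (clh + clr) / Vc
      fr <- clr / (clh + clr)
      sol <- .solve_turnover_grid(o$grid, kel, fr, ksyn, Vc, C0)
      if (nrow(o$Ybm))
        nll <- nll + .res_nll(o$Ybm, sol$C[o$bm_idx, , drop = FALSE], sig_pl, 0)
      if (nrow(o$Yur)) {
        P <- sol$A_renal[o$ur_i1, , drop = FALSE] - sol$A_renal[o$ur_i0, , drop = FALSE]
        nll <- nll + .res_nll(o$Yur, P, sig_ur, 0)
      }
    }
  }
  nll + .eta_prior_nll(eta, omega)
}

.fit_biomarker <- function(ctxs, pop, ctrl) {
  init <- c(log(pop$fixed[["ksyn"]]), log(pop$fixed[["CLh"]]),
            log(pop$fixed[["CLR"]]), log(pop$fixed[["Ki_u_OATP1B3"]]),
            log(pop$fixed[["Ki_u_OAT3"]]), log(pop$fixed[["X"]] - 1),
            log(pop$residual$biomarker_plasma$prop),
            log(pop$residual$biomarker_urine$prop),
            log(pop$iiv[["ksyn"]]), log(pop$iiv[["CLR"]]),
            log(pop$iiv[["Ki_u_OAT3"]]))
  names(init) <- c("ksyn", "CLh", "CLR", "Ki_u_OATP1B3", "Ki_u_OAT3", "Xm1",
                   "sigma_prop_bm_plasma", "sigma_prop_bm_urine",
                   "om_ksyn", "om_CLR", "om_Ki_u_OAT3")
  init <- init + ctrl$init_shift[seq_along(init) %% 2 + 1]
  Vc <- pop$fixed[["Vc"]]
  warm <- new.env()
  obj <- function(tp, inner_maxit = ctrl$inner_maxit, gtol = ctrl$inner_gtol) {
    th <- c(ksyn = exp(tp[[1]]), CLh = exp(tp[[2]]), CLR = exp(tp[[3]]),
            Ki_u_OATP1B3 = exp(tp[[4]]), Ki_u_OAT3 = exp(tp[[5]]),
            X = 1 + exp(tp[[6]]))
    sig_pl <- exp(tp[[7]]); sig_ur <- exp(tp[[8]])
    omega <- exp(tp[9:11])
    total <- 0
    for (gi in seq_along(ctxs)) {
      ctx <- ctxs[[gi]]
      f <- function(eta) .bm_group_nll(ctx, eta, th, Vc, sig_pl, sig_ur, omega)
      eta0 <- if (!is.null(warm[[as.character(gi)]])) warm[[as.character(gi)]]
              else matrix(0, 3, ctx$ns)
      vn <- .vnewton(f, eta0, maxit = inner_maxit, gtol = gtol)
      warm[[as.character(gi)]] <- vn$eta
      total <- total + sum(vn$val + 0.5 * vn$logdet - 1.5 * log(2 * pi))
    }
    total
  }
  opt <- stats::nlminb(init, obj, control = list(iter.max = ctrl$iter.max,
                                                 eval.max = ctrl$eval.max,
                                                 rel.tol = ctrl$rel.tol))
  obj(opt$par)   # refresh conditional modes at the optimum
  ebes <- list()
  for (gi in seq_along(ctxs)) {
    eta <- warm[[as.character(gi)]]
    for (i in seq_along(ctxs[[gi]]$keys))
      ebes[[ctxs[[gi]]$keys[i]]] <- c(eta_ksyn = eta[1, i],
                                      eta_CLR = eta[2, i],
                                      eta_Ki_u_OAT3 = eta[3, i])
  }
  tp <- opt$par
  par <- c(ksyn = exp(tp[[1]]), CLh = exp(tp[[2]]), CLR = exp(tp[[3]]),
           Ki_u_OATP1B3 = exp(tp[[4]]), Ki_u_OAT3 = exp(tp[[5]]),
           X = 1 + exp(tp[[6]]),
           sigma_prop_bm_plasma = exp(tp[[7]]), sigma_prop_bm_urine = exp(tp[[8]]),
           om_ksyn = exp(tp[[9]]), om_CLR = exp(tp[[10]]),
           om_Ki_u_OAT3 = exp(tp[[11]]))
  list(par = par, objective = opt$objective, obj_fun = obj, tpar = tp,
       convergence = opt$convergence, ebes = ebes, message = opt$message,
       d_eta = 3)
}

# Central finite-difference Hessian of a scalar function.
.fd_hessian <- function(fn, x, h = 2e-3) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- fn(x)
  for (j in seq_len(p)) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    H[j, j] <- (fn(xp) - 2 * f0 + fn(xm)) / h^2
  }
  if (p > 1) {
    for (j in seq_len(p - 1)) for (k in (j + 1):p) {
      xpp <- x; xpp[c(j, k)] <- xpp[c(j, k)] + h
      xpm <- x; xpm[j] <- xpm[j] + h; xpm[k] <- xpm[k] - h
      xmp <- x; xmp[j] <- xmp[j] - h; xmp[k] <- xmp[k] + h
      xmm <- x; xmm[c(j, k)] <- xmm[c(j, k)] - h
      H[j, k] <- H[k, j] <- (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h^2)
    }
  }
  H
}

# RSE (%) on the natural scale from the Hessian of the nll over transformed
# (log or log(X-1)) parameters.
.rse_from_hessian <- function(H, tpar, xm1_names = "Xm1") {
  cv <- tryCatch(solve(.make_pd(H)), error = function(e) NULL)
  if (is.null(cv)) return(rep(NA_real_, length(tpar)))
  se <- sqrt(pmax(diag(cv), 0))
  rse <- 100 * se
  for (nm in intersect(xm1_names, names(tpar))) {
    i <- match(nm, names(tpar))
    X <- 1 + exp(tpar[[i]])
    rse[i] <- 100 * se[i] * (X - 1) / X   # delta method for X = 1 + exp(t)
  }
  names(rse) <- names(tpar)
  rse
}

#' Control settings for the mixed-effects fit
#'
#' @param iter.max,eval.max,rel.tol Outer `nlminb` controls.
#' @param inner_maxit Maximum Newton iterations of the inner
#'   (empirical-Bayes) mode search per outer evaluation.
#' @param inner_gtol Gradient-norm convergence tolerance of the inner mode
#'   search (tightened automatically for the Fisher-information pass).
#' @param grid_step Solver grid spacing (h) used during fitting.
#' @param init_shift Log-scale offsets (recycled over parameters) applied to
#'   the initial values so the optimizer never starts exactly at the truth
#'   in simulation-re-estimation exercises.
#' @param compute_rse Compute relative standard errors from the inverse
#'   observed Fisher information (adds a finite-difference Hessian pass)?
#' @return A list of control settings.
#' @export
fit_control <- function(iter.max = 45, eval.max = 280, rel.tol = 1e-5,
                        inner_maxit = 20, inner_gtol = 1e-3, grid_step = 0.1,
                        init_shift = c(0.2, -0.2), compute_rse = FALSE) {
  list(iter.max = iter.max, eval.max = eval.max, rel.tol = rel.tol,
       inner_maxit = inner_maxit, inner_gtol = inner_gtol,
       grid_step = grid_step, init_shift = init_shift,
       compute_rse = compute_rse)
}

#' Fit the coupled population models to one or more datasets
#'
#' Sequential (IPP) maximum-marginal-likelihood estimation by the Laplace
#' approximation: the rifampicin and probenecid one-compartment models are
#' fitted to their plasma data first; individual inhibitor concentration
#' profiles (empirical-Bayes) then drive the biomarker turnover model fit,
#' which estimates the synthesis rate, the two elimination clearances, both
#' unbound inhibition constants, the probenecid hepatic factor X, residual
#' error magnitudes and the IIV terms. `Vc` and the inhibitor additive error
#' components are fixed, mirroring the reference analysis.
#'
#' @param datasets A records data frame or a list of them (IDs may repeat
#'   across list elements; each element is treated as a separate study).
#' @param pop Initial values and constants, see [default_population()].
#' @param control See [fit_control()].
#' @return A `fit_result` list: `estimates` (updated population object),
#'   `stages` (per-stage parameter vectors, convergence and, when requested,
#'   RSE%), `rse` (combined named vector, biomarker stage first), `ofv`
#'   (-2 log marginal likelihood, all stages), `ebes`, `strategy`,
#'   `convergence`.
#' @export
fit_population <- function(datasets, pop = default_population(),
                           control = fit_control()) {
  subjects <- .parse_subjects(datasets)
  if (!length(subjects)) stop("no subjects found in the datasets")
  groups <- .group_subjects(subjects)

  rif_groups <- .inh_groups(groups, "rif")
  prob_groups <- .inh_groups(groups, "prob")
  stages <- list()
  inh_ebes <- list()
  if (length(rif_groups)) {
    stages$rifampicin <- .fit_rifampicin(rif_groups, pop, control)
    inh_ebes <- c(inh_ebes, stages$rifampicin$ebes)
  }
  if (length(prob_groups)) {
    stages$probenecid <- .fit_probenecid(prob_groups, pop, control)
    for (k in names(stages$probenecid$ebes))
      inh_ebes[[k]] <- c(inh_ebes[[k]], stages$probenecid$ebes[[k]])
  }
  ctxs <- .bm_contexts(groups, pop, inh_ebes, control$grid_step)
  stages$biomarker <- .fit_biomarker(ctxs, pop, control)

  if (isTRUE(control$compute_rse)) {
    for (st in names(stages)) {
      of <- stages[[st]]$obj_fun
      tight <- function(x) of(x, inner_maxit = 40, gtol = 1e-5)
      H <- .fd_hessian(tight, stages[[st]]$tpar, h = 2e-3)
      stages[[st]]$rse <- .rse_from_hessian(H, stages[[st]]$tpar)
    }
  }

  est <- pop
  bm <- stages$biomarker$par
  est$fixed[c("ksyn", "CLh", "CLR", "Ki_u_OATP1B3", "Ki_u_OAT3", "X")] <-
    bm[c("ksyn", "CLh", "CLR", "Ki_u_OATP1B3", "Ki_u_OAT3", "X")]
  est$residual$biomarker_plasma$prop <- bm[["sigma_prop_bm_plasma"]]
  est$residual$biomarker_urine$prop <- bm[["sigma_prop_bm_urine"]]
  est$iiv[c("ksyn", "CLR", "Ki_u_OAT3")] <-
    bm[c("om_ksyn", "om_CLR", "om_Ki_u_OAT3")]
  if (!is.null(stages$rifampicin)) {
    rp <- stages$rifampicin$par
    est$fixed[c("Tlag_RIF", "Tk0_RIF", "V_RIF", "CL_RIF")] <-
      rp[c("Tlag_RIF", "Tk0_RIF", "V_RIF", "CL_RIF")]
    est$residual$rifampicin_plasma$prop <- rp[["sigma_prop_RIF"]]
    est$iiv[c("Tlag_RIF", "Tk0_RIF", "CL_RIF")] <-
      rp[c("om_Tlag_RIF", "om_Tk0_RIF", "om_CL_RIF")]
  }
  if (!is.null(stages$probenecid)) {
    pp <- stages$probenecid$par
    est$fixed[c("ka_PROB", "V_PROB", "CL_PROB")] <-
      pp[c("ka_PROB", "V_PROB", "CL_PROB")]
    est$residual$probenecid_plasma$prop <- pp[["sigma_prop_PROB"]]
    est$iiv[c("V_PROB", "CL_PROB")] <- pp[c("om_V_PROB", "om_CL_PROB")]
  }

  rse <- unlist(lapply(stages, function(s) s$rse))
  conv <- vapply(stages, function(s) s$convergence, numeric(1))
  out <- list(estimates = est, stages = stages,
              rse = if (length(rse)) rse else NULL,
              ofv = 2 * sum(vapply(stages, `[[`, numeric(1), "objective")),
              ebes = stages$biomarker$ebes,
              strategy = "sequential-IPP (Laplace)",
              convergence = conv)
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Population fit (", x$strategy, ")\n", sep = "")
  cat("OFV (-2 log marginal likelihood):", round(x$ofv, 2), "\n")
  for (st in names(x$stages)) {
    cat(sprintf("-- %s stage (convergence %d)\n", st, x$stages[[st]]$convergence))
    tab <- signif(x$stages[[st]]$par, 4)
    if (!is.null(x$stages[[st]]$rse))
      tab <- cbind(estimate = tab, `RSE%` = round(x$stages[[st]]$rse, 1))
    print(tab)
  }
  invisible(x)
}

# ---- per-subject utilities ------------------------------------------------

# Build a single-subject biomarker context (shared by individual_nll,
# empirical_bayes and gof).
.single_ctx <- function(sub_records, pop, inh_params = NULL, grid_step = 0.05) {
  subjects <- .parse_subjects(sub_records)
  if (length(subjects) != 1)
    stop("expected records of exactly one subject")
  key <- subjects[[1]]$key
  ebes <- list()
  ebes[[key]] <- inh_params
  .bm_contexts(.group_subjects(subjects), pop, ebes, grid_step)[[1]]
}

#' Joint individual negative log likelihood of the biomarker model
#'
#' The inner objective of the Laplace method for one subject: the Gaussian
#' residual negative log density of the subject's biomarker observations
#' given random effects `eta`, plus the negative log prior of `eta`. The
#' random effects are, in order, the log-scale perturbations of `ksyn`,
#' `CLR` and `Ki_u_OAT3`.
#'
#' @param sub_records Records of a single subject (dose rows included).
#' @param eta Numeric length-3 random-effect vector.
#' @param pop Population parameters (typical values, IIV, residuals).
#' @param inh_params Optional named vector of that subject's individual
#'   inhibitor parameters (defaults to typical values).
#' @param grid_step Solver grid spacing (h).
#' @return Scalar negative log joint density.
#' @export
individual_nll <- function(sub_records, eta, pop = default_population(),
                           inh_params = NULL, grid_step = 0.05) {
  ctx <- .single_ctx(sub_records, pop, inh_params, grid_step)
  val <- .bm_group_nll(ctx, matrix(eta, 3, 1), pop$fixed,
                       pop$fixed[["Vc"]],
                       pop$residual$biomarker_plasma$prop,
                       pop$residual$biomarker_urine$prop,
                       pop$iiv[c("ksyn", "CLR", "Ki_u_OAT3")])
  if (!is.finite(val)) stop("non-finite individual likelihood (check records)")
  as.numeric(val)
}

#' Empirical-Bayes (MAP) random effects for one subject
#'
#' @inheritParams individual_nll
#' @return Named length-3 vector of MAP random effects.
#' @export
empirical_bayes <- function(sub_records, pop = default_population(),
                            inh_params = NULL, grid_step = 0.05) {
  ctx <- .single_ctx(sub_records, pop, inh_params, grid_step)
  f <- function(eta) .bm_group_nll(ctx, eta, pop$fixed, pop$fixed[["Vc"]],
                                   pop$residual$biomarker_plasma$prop,
                                   pop$residual$biomarker_urine$prop,
                                   pop$iiv[c("ksyn", "CLR", "Ki_u_OAT3")])
  vn <- .vnewton(f, matrix(0, 3, 1), maxit = 25)
  stats::setNames(vn$eta[, 1], c("eta_ksyn", "eta_CLR", "eta_Ki_u_OAT3"))
}

#' Goodness-of-fit table
#'
#' Population (random effects at zero) and individual (empirical-Bayes)
#' predictions with weighted residuals for every biomarker observation.
#'
#' @param datasets A records data frame or list of them.
#' @param fit A [fit_population()] result (its estimates and EBEs are used).
#' @param grid_step Solver grid spacing (h).
#' @return Data frame with one row per biomarker observation: subject key,
#'   `OCC`, `TIME`, `DVID`, `DV`, `PRED`, `IPRED`, `WRES`
#'   (`(DV - PRED)/sd(PRED)`), `IWRES`.
#' @export
gof <- function(datasets, fit, grid_step = 0.05) {
  pop <- fit$estimates
  subjects <- .parse_subjects(datasets)
  out <- list()
  for (s in subjects) {
    inh <- .inh_params_for(s, fit)
    ctx <- .single_ctx(.records_of(s), pop, inh, grid_step)
    eb <- fit$ebes[[s$key]]
    eta1 <- if (!is.null(eb)) matrix(eb, 3, 1) else matrix(0, 3, 1)
    p0 <- .bm_predictions(ctx, matrix(0, 3, 1), pop)
    p1 <- .bm_predictions(ctx, eta1, pop)
    tab <- .obs_table(s)
    if (!nrow(tab)) next
    sig <- ifelse(tab$DVID == 1, pop$residual$biomarker_plasma$prop,
                  pop$residual$biomarker_urine$prop)
    tab$PRED <- p0; tab$IPRED <- p1
    tab$WRES <- (tab$DV - tab$PRED) / sqrt(.res_var(tab$PRED, sig, 0))
    tab$IWRES <- (tab$DV - tab$IPRED) / sqrt(.res_var(tab$IPRED, sig, 0))
    out[[s$key]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# biomarker predictions stacked in the same order as .obs_table
.bm_predictions <- function(ctx, eta, pop) {
  th <- pop$fixed
  ksyn <- th[["ksyn"]] * exp(eta[1, 1])
  CLR <- th[["CLR"]] * exp(eta[2, 1])
  Ki3 <- th[["Ki_u_OAT3"]] * exp(eta[3, 1])
  CLh <- th[["CLh"]]; Vc <- th[["Vc"]]
  C0 <- ksyn / (CLh + CLR)
  preds <- list()
  for (oc in names(ctx$occs)) {
    o <- ctx$occs[[oc]]
    if (o$type == "const") {
      preds[[oc]] <- c(rep(C0, o$n_bm), o$ur_w * C0 * CLR)
    } else {
      mh <- 1 / ((if (o$prob_occ) th[["X"]] else 1) * (1 + o$Curif / th[["Ki_u_OATP1B3"]]))
      mr <- 1 / (1 + o$Cuprob / Ki3)
      clh <- CLh * mh; clr <- CLR * mr
      kel <- (clh + clr) / Vc
      fr <- clr / (clh + clr)
      sol <- .solve_turnover_grid(o$grid, kel, fr, ksyn, Vc, C0)
      pu <- if (length(o$ur_i1)) sol$A_renal[o$ur_i1, 1] - sol$A_renal[o$ur_i0, 1] else numeric(0)
      preds[[oc]] <- c(sol$C[o$bm_idx, 1], pu)
    }
  }
  unlist(preds, use.names = FALSE)
}

.obs_table <- function(s) {
  rows <- list()
  for (oc in names(s$occasions)) {
    o <- s$occasions[[oc]]
    if (nrow(o$bm))
      rows[[paste0(oc, "b")]] <- data.frame(key = s$key, OCC = o$occ,
                                            TIME = o$bm$TIME, DVID = 1L,
                                            DV = o$bm$DV)
    if (nrow(o$ur))
      rows[[paste0(oc, "u")]] <- data.frame(key = s$key, OCC = o$occ,
                                            TIME = o$ur$TIME, DVID = 2L,
                                            DV = o$ur$DV)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(key = character(0), OCC = integer(0), TIME = numeric(0),
               DVID = integer(0), DV = numeric(0))
}

.records_of <- function(s) {
  rows <- list()
  for (oc in names(s$occasions)) {
    o <- s$occasions[[oc]]
    add <- function(df) if (nrow(df)) rows[[length(rows) + 1L]] <<- df
    if (nrow(o$rif_doses))
      add(data.frame(ID = s$id, OCC = o$occ, TIME = o$rif_doses$TIME, EVID = 1L,
                     DVID = NA_integer_, DV = NA_real_, AMT = o$rif_doses$AMT,
                     DRUG = "RIF", USTART = NA_real_))
    if (nrow(o$prob_doses))
      add(data.frame(ID = s$id, OCC = o$occ, TIME = o$prob_doses$TIME, EVID = 1L,
                     DVID = NA_integer_, DV = NA_real_, AMT = o$prob_doses$AMT,
                     DRUG = "PROB", USTART = NA_real_))
    if (nrow(o$bm))
      add(data.frame(ID = s$id, OCC = o$occ, TIME = o$bm$TIME, EVID = 0L,
                     DVID = 1L, DV = o$bm$DV, AMT = NA_real_,
                     DRUG = NA_character_, USTART = NA_real_))
    if (nrow(o$ur))
      add(data.frame(ID = s$id, OCC = o$occ, TIME = o$ur$TIME, EVID = 0L,
                     DVID = 2L, DV = o$ur$DV, AMT = NA_real_,
                     DRUG = NA_character_, USTART = o$ur$USTART))
    if (nrow(o$rif))
      add(data.frame(ID = s$id, OCC = o$occ, TIME = o$rif$TIME, EVID = 0L,
                     DVID = 3L, DV = o$rif$DV, AMT = NA_real_,
                     DRUG = NA_character_, USTART = NA_real_))
    if (nrow(o$prob))
      add(data.frame(ID = s$id, OCC = o$occ, TIME = o$prob$TIME, EVID = 0L,
                     DVID = 4L, DV = o$prob$DV, AMT = NA_real_,
                     DRUG = NA_character_, USTART = NA_real_))
  }
  d <- do.call(rbind, rows)
  d[order(d$ID, d$OCC, d$TIME), , drop = FALSE]
}

.inh_params_for <- function(s, fit) {
  out <- c()
  if (!is.null(fit$stages$rifampicin))
    out <- c(out, fit$stages$rifampicin$ebes[[s$key]])
  if (!is.null(fit$stages$probenecid))
    out <- c(out, fit$stages$probenecid$ebes[[s$key]])
  out
}
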