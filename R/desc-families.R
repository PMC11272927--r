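# The 2D descriptor families. Each family exposes a static name vector and a
# compute function over (graph context, molecule-level aux data); the catalogue
# is the concatenation of all families (1613 descriptors).

.AC_FAMS <- c("ATS", "AATS", "ATSC", "AATSC")
.AC_LAGS <- 0:10
.MG_LAGS <- 1:10

.autocorr_names <- function() {
  nm <- character(0)
  for (wc in .WEIGHT_CODES) {
    for (f in .AC_FAMS) nm <- c(nm, paste0(f, .AC_LAGS, wc))
    nm <- c(nm, paste0("MATS", .MG_LAGS, wc), paste0("GATS", .MG_LAGS, wc))
  }
  nm
}

.autocorr_compute <- function(ctx, aux) {
  out <- setNames(rep(NA_real_, length(.autocorr_names())), .autocorr_names())
  n <- ctx$n
  D <- ctx$D
  ut <- upper.tri(D)
  for (wc in .WEIGHT_CODES) {
    w <- ctx$W[, wc]
    if (any(is.na(w))) next
    wcen <- w - mean(w)
    ssc <- sum(wcen^2)
    out[paste0("ATS0", wc)] <- sum(w^2)
    out[paste0("AATS0", wc)] <- sum(w^2) / n
    out[paste0("ATSC0", wc)] <- ssc
    out[paste0("AATSC0", wc)] <- ssc / n
    for (k in setdiff(.AC_LAGS, 0)) {
      sel <- ut & D == k
      np <- sum(sel)
      if (np == 0) next
      ij <- which(sel, arr.ind = TRUE)
      ats <- sum(w[ij[, 1]] * w[ij[, 2]])
      atsc <- sum(wcen[ij[, 1]] * wcen[ij[, 2]])
      out[paste0("ATS", k, wc)] <- ats
      out[paste0("AATS", k, wc)] <- ats / np
      out[paste0("ATSC", k, wc)] <- atsc
      out[paste0("AATSC", k, wc)] <- atsc / np
      if (ssc > 0 && n > 1) {
        out[paste0("MATS", k, wc)] <- (atsc / np) / (ssc / n)
        gnum <- sum((w[ij[, 1]] - w[ij[, 2]])^2) / (2 * np)
        out[paste0("GATS", k, wc)] <- gnum / (ssc / (n - 1))
      }
    }
  }
  out
}

.BARYSZ_W <- c("Z", "m", "v", "se", "pe", "are", "p", "i")

.spectral_names <- function() {
  base <- c(
    "SpAbs", "SpMax", "SpDiam", "SpAD", "SpMAD", "LogEE", "SM1",
    "VE1", "VE2", "VE3", "VR1", "VR2", "VR3"
  )
  c(
    paste0(base, "_A"), paste0(base, "_L"), paste0(base, "_Ln"),
    paste0(base, "_D"), paste0(base, "_H"),
    unlist(lapply(.BARYSZ_W, function(w) paste0(base, "_Dz", w))),
    unlist(lapply(.WEIGHT_CODES, function(w) paste0(base, "_B", w)))
  )
}

.spectral_compute <- function(ctx, aux) {
  n <- ctx$n
  A <- ctx$A
  deg <- ctx$deg
  L <- diag(deg, n) - A
  Ln <- {
    s <- ifelse(deg > 0, 1 / sqrt(deg), 0)
    diag(n) - diag(s, n) %*% A %*% diag(s, n)
  }
  Dm <- if (ctx$connected) ctx$D else NULL
  Hm <- if (ctx$connected) {
    H <- 1 / ctx$D; diag(H) <- 0; H
  } else {
    NULL
  }
  out <- c(
    spectral_suite(A, ctx, "A"), spectral_suite(L, ctx, "L"),
    spectral_suite(Ln, ctx, "Ln"), spectral_suite(Dm, ctx, "D"),
    spectral_suite(Hm, ctx, "H")
  )
  for (w in .BARYSZ_W) {
    out <- c(out, spectral_suite(barysz_matrix(ctx, w), ctx, paste0("Dz", w)))
  }
  for (w in .WEIGHT_CODES) {
    out <- c(out, spectral_suite(burden_matrix(ctx, w), ctx, paste0("B", w)))
  }
  out
}

.chi_names <- function() {
  c(
    paste0("Xp", 0:7), paste0("Xpv", 0:7), paste0("AXp", 0:7), paste0("AXpv", 0:7),
    paste0("Xch", 3:7), paste0("Xchv", 3:7)
  )
}

.chi_compute <- function(ctx, aux) {
  out <- setNames(rep(NA_real_, length(.chi_names())), .chi_names())
  d <- ctx$delta; dv <- ctx$deltav
  if (all(d > 0)) {
    out["Xp0"] <- sum(1 / sqrt(d))
    out["AXp0"] <- out["Xp0"] / ctx$n
  }
  if (all(dv > 0)) {
    out["Xpv0"] <- sum(1 / sqrt(dv))
    out["AXpv0"] <- out["Xpv0"] / ctx$n
  }
  ps <- aux$paths
  for (h in 1:7) {
    cnt <- ps$count[h]
    out[paste0("Xp", h)] <- if (cnt > 0) ps$chi[h] else 0
    out[paste0("Xpv", h)] <- if (cnt > 0) ps$chiv[h] else 0
    out[paste0("AXp", h)] <- if (cnt > 0) ps$chi[h] / cnt else NA_real_
    out[paste0("AXpv", h)] <- if (cnt > 0) ps$chiv[h] / cnt else NA_real_
  }
  cs <- aux$cycles
  for (s in 3:7) {
    out[paste0("Xch", s)] <- cs$chi[s]
    out[paste0("Xchv", s)] <- cs$chiv[s]
  }
  out
}

# Kier alpha: covalent-radius ratio to sp3 carbon, by element and hybridization
.kier_alpha <- function(ctx) {
  r <- vapply(seq_len(ctx$n), function(i) {
    e <- ctx$elem[i]; h <- ctx$hyb[i]
    switch(e,
      C = c(0.60, 0.67, 0.77)[h],
      N = c(0.55, 0.62, 0.74)[h],
      O = c(0.62, 0.62, 0.74)[h],
      F = 0.72, Cl = 0.99, Br = 1.14, I = 1.33,
      S = 1.04, P = 1.10, Si = 1.17, B = 0.88, Se = 1.17, As = 1.19,
      NA_real_
    )
  }, numeric(1))
  sum(r / 0.77 - 1, na.rm = TRUE)
}

.kappa_names <- function() c(paste0("Kier", 1:3), paste0("KierA", 1:3))

.kappa_compute <- function(ctx, aux) {
  out <- setNames(rep(NA_real_, 6), .kappa_names())
  n <- ctx$n
  p1 <- nrow(ctx$bonds)
  p2 <- aux$paths$count[2]
  p3 <- aux$paths$count[3]
  a <- .kier_alpha(ctx)
  if (p1 > 0) {
    out["Kier1"] <- n * (n - 1)^2 / p1^2
    out["KierA1"] <- (n + a) * (n + a - 1)^2 / (p1 + a)^2
  }
  if (p2 > 0) {
    out["Kier2"] <- (n - 1) * (n - 2)^2 / p2^2
    out["KierA2"] <- (n + a - 1) * (n + a - 2)^2 / (p2 + a)^2
  }
  if (p3 > 0) {
    k3 <- if (n %% 2 == 1) (n - 1) * (n - 3)^2 else (n - 3) * (n - 2)^2
    ka3 <- if (n %% 2 == 1) (n + a - 1) * (n + a - 3)^2 else (n + a - 3) * (n + a - 2)^2
    out["Kier3"] <- k3 / p3^2
    out["KierA3"] <- ka3 / (p3 + a)^2
  }
  out
}

.pathcount_names <- function() c(paste0("MPC", 1:10), "TMPC", paste0("piPC", 1:10), "TpiPC")

.pathcount_compute <- function(ctx, aux) {
  ps <- aux$paths
  out <- setNames(rep(NA_real_, 22), .pathcount_names())
  out[paste0("MPC", 1:10)] <- ps$count
  out["TMPC"] <- sum(ps$count)
  out[paste0("piPC", 1:10)] <- log1p(ps$pic)
  out["TpiPC"] <- log1p(sum(ps$pic))
  out
}

.walk_names <- function() c(paste0("MWC", 1:10), "TWC", paste0("SRW", 2:10), "TSRW")

.walk_compute <- function(ctx, aux) {
  out <- setNames(rep(NA_real_, 21), .walk_names())
  A <- ctx$A
  P <- diag(ctx$n)
  walks <- numeric(10); srw <- numeric(10)
  for (h in 1:10) {
    P <- P %*% A
    walks[h] <- sum(P) / 2
    srw[h] <- sum(diag(P))
  }
  out[paste0("MWC", 1:10)] <- log1p(walks)
  out["TWC"] <- log1p(sum(walks))
  out[paste0("SRW", 2:10)] <- log1p(srw[2:10])
  out["TSRW"] <- log1p(sum(srw[2:10]))
  out
}

.IC_KINDS <- c("IC", "TIC", "SIC", "CIC", "BIC")

.ic_names <- function() unlist(lapply(0:7, function(r) paste0(.IC_KINDS, r)))

.ic_compute <- function(ctx, aux) {
  out <- setNames(rep(NA_real_, 40), .ic_names())
  n <- ctx$n
  m <- nrow(ctx$bonds)
  code <- paste(ctx$elem, ctx$deg, ctx$nH, ctx$fq)
  adj <- lapply(seq_len(n), function(i) which(ctx$A[i, ] > 0))
  for (r in 0:7) {
    p <- table(code) / n
    ic <- -sum(p * log2(p))
    out[paste0("IC", r)] <- ic
    out[paste0("TIC", r)] <- n * ic
    if (n > 1) out[paste0("SIC", r)] <- ic / log2(n)
    if (n > 1) out[paste0("CIC", r)] <- log2(n) - ic
    if (m > 1) out[paste0("BIC", r)] <- ic / log2(m)
    # Weisfeiler-Lehman style refinement for the next order
    code <- vapply(seq_len(n), function(i) {
      paste(code[i], paste(sort(code[adj[[i]]]), collapse = "|"))
    }, "")
    code <- as.character(factor(code))
  }
  out
}

.ESTATE_SPECIFIC <- c(
  "sCH3", "ssCH2", "sssCH", "ssssC", "dCH2", "dsCH", "dssC", "tCH", "tsC",
  "aCH", "aasC", "aaaC",
  "sNH2", "ssNH", "sssN", "dNH", "dsN", "tN", "aNH", "aaN",
  "sOH", "ssO", "dO", "aO",
  "sSH", "ssS", "dS", "ddssS", "aS",
  "sssP", "dsssP",
  "sF", "sCl", "sBr", "sI"
)

.ESTATE_AGG <- c(
  "any", "allC", "allN", "allO", "allS", "allP", "allHal", "hetero", "arom",
  "aliph", "ring", "nonring", "terminal", "branch", "Csp3", "Csp2", "Csp",
  "Nsp3", "Nsp2", "Osp3", "Osp2", "donorH", "acceptor", "charged", "HETarom"
)

.estate_names <- function() {
  unlist(lapply(
    c(.ESTATE_SPECIFIC, .ESTATE_AGG),
    function(t) paste0(c("N_", "S_", "Min_", "Max_"), t)
  ))
}

.estate_atom_type <- function(ctx, i) {
  e <- ctx$elem[i]; a <- ctx$arom[i]; h <- ctx$hyb[i]
  dg <- ctx$deg[i]; nh <- ctx$nH[i]
  if (e == "C") {
    if (a) {
      nab <- if (nrow(ctx$bonds)) sum(ctx$bonds$arom & (ctx$bonds$i == i | ctx$bonds$j == i)) else 0
      if (nh > 0) return("aCH")
      return(if (nab >= 3) "aaaC" else "aasC")
    }
    if (h == 3 && dg >= 1 && dg <= 4) return(c("sCH3", "ssCH2", "sssCH", "ssssC")[dg])
    if (h == 2 && dg >= 1 && dg <= 3) return(c("dCH2", "dsCH", "dssC")[dg])
    if (h == 1 && dg >= 1 && dg <= 2) return(c("tCH", "tsC")[dg])
    return(NA_character_)
  }
  if (e == "N") {
    if (a) return(if (nh > 0) "aNH" else "aaN")
    if (h == 1) return("tN")
    if (h == 2) return(if (dg <= 1) "dNH" else "dsN")
    if (dg >= 1 && dg <= 3) return(c("sNH2", "ssNH", "sssN")[dg])
    return(NA_character_)
  }
  if (e == "O") {
    if (a) return("aO")
    if (nh > 0) return("sOH")
    if (dg >= 2) return("ssO")
    if (dg == 1) return("dO")
    return(NA_character_)
  }
  if (e == "S") {
    if (a) return("aS")
    if (dg <= 1 && nh > 0) return("sSH")
    if (dg <= 1) return("dS")
    if (dg == 2) return("ssS")
    return("ddssS")
  }
  if (e == "P") return(if (ctx$deg[i] <= 3) "sssP" else "dsssP")
  if (e %in% c("F", "Cl", "Br", "I")) return(paste0("s", e))
  NA_character_
}

.estate_compute <- function(ctx, aux) {
  nm <- .estate_names()
  out <- setNames(rep(NA_real_, length(nm)), nm)
  S <- ctx$estate
  types <- vapply(seq_len(ctx$n), function(i) .estate_atom_type(ctx, i), "")
  inring <- aux$inring
  agg <- list(
    any = rep(TRUE, ctx$n),
    allC = ctx$elem == "C", allN = ctx$elem == "N", allO = ctx$elem == "O",
    allS = ctx$elem == "S", allP = ctx$elem == "P",
    allHal = ctx$elem %in% c("F", "Cl", "Br", "I"),
    hetero = ctx$elem != "C", arom = ctx$arom, aliph = !ctx$arom,
    ring = inring, nonring = !inring,
    terminal = ctx$deg == 1, branch = ctx$deg >= 3,
    Csp3 = ctx$elem == "C" & ctx$hyb == 3 & !ctx$arom,
    Csp2 = ctx$elem == "C" & (ctx$hyb == 2 | ctx$arom),
    Csp = ctx$elem == "C" & ctx$hyb == 1,
    Nsp3 = ctx$elem == "N" & ctx$hyb == 3 & !ctx$arom,
    Nsp2 = ctx$elem == "N" & (ctx$hyb == 2 | ctx$arom),
    Osp3 = ctx$elem == "O" & ctx$hyb == 3 & !ctx$arom,
    Osp2 = ctx$elem == "O" & (ctx$hyb == 2 | ctx$arom),
    donorH = ctx$elem %in% c("N", "O", "S") & ctx$nH > 0,
    acceptor = ctx$elem %in% c("N", "O"),
    charged = ctx$fq != 0,
    HETarom = ctx$arom & ctx$elem != "C"
  )
  fill <- function(tag, members) {
    out[paste0("N_", tag)] <<- sum(members)
    if (any(members) && all(is.finite(S[members]))) {
      out[paste0("S_", tag)] <<- sum(S[members])
      out[paste0("Min_", tag)] <<- min(S[members])
      out[paste0("Max_", tag)] <<- max(S[members])
    }
  }
  for (t in .ESTATE_SPECIFIC) fill(t, !is.na(types) & types == t)
  for (t in .ESTATE_AGG) fill(t, agg[[t]])
  out
}

.ringcount_names <- function() {
  c("nRing", "nRingAtoms", "nAromAtom", "nAromBond", paste0("nR", 3:12))
}

.ringcount_compute <- function(ctx, aux) {
  out <- setNames(rep(NA_real_, 14), .ringcount_names())
  ncomp <- igraph::components(ctx$ig)$no
  out["nRing"] <- nrow(ctx$bonds) - ctx$n + ncomp
  out["nRingAtoms"] <- sum(aux$inring)
  out["nAromAtom"] <- sum(ctx$arom)
  out["nAromBond"] <- if (nrow(ctx$bonds)) sum(ctx$bonds$arom) else 0
  out[paste0("nR", 3:12)] <- aux$rings
  out
}

.atomcount_names <- function() {
  c(
    "nAtom", "nHeavy", "nHAtom", "nB", "nC", "nN", "nO", "nS", "nP",
    "nF", "nCl", "nBr", "nI", "nSi", "nX", "nHet"
  )
}

.atomcount_compute <- function(ctx, aux) {
  e <- ctx$elem
  cnt <- function(x) sum(e == x)
  setNames(c(
    ctx$n + sum(ctx$nH), ctx$n, sum(ctx$nH), cnt("B"), cnt("C"), cnt("N"),
    cnt("O"), cnt("S"), cnt("P"), cnt("F"), cnt("Cl"), cnt("Br"), cnt("I"),
    cnt("Si"), sum(e %in% c("F", "Cl", "Br", "I")), sum(e != "C")
  ), .atomcount_names())
}

.bondcount_names <- function() {
  c(
    "nBond", "nBondS", "nBondD", "nBondT", "nBondA", "nBondM",
    "nBondAmide", "nBondRot"
  )
}

.bondcount_compute <- function(ctx, aux) {
  b <- ctx$bonds
  inring_bond <- if (nrow(b)) {
    br <- igraph::bridges(ctx$ig)
    el <- igraph::as_edgelist(ctx$ig)
    key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    ringkey <- key[setdiff(seq_len(nrow(el)), as.integer(br))]
    paste(pmin(b$i, b$j), pmax(b$i, b$j)) %in% ringkey
  } else {
    logical(0)
  }
  rot <- if (nrow(b)) {
    b$type == "1" & !inring_bond & ctx$deg[b$i] >= 2 & ctx$deg[b$j] >= 2
  } else {
    logical(0)
  }
  setNames(c(
    nrow(b), sum(b$type == "1"), sum(b$type == "2"), sum(b$type == "3"),
    sum(b$type == "ar"), sum(b$type %in% c("2", "3", "ar")),
    sum(b$type == "am"), sum(rot)
  ), .bondcount_names())
}

.carbontype_names <- function() {
  c(
    "C1SP1", "C2SP1", "C1SP2", "C2SP2", "C3SP2", "C1SP3", "C2SP3",
    "C3SP3", "C4SP3", "FCSP3"
  )
}

.carbontype_compute <- function(ctx, aux) {
  out <- setNames(rep(0, 10), .carbontype_names())
  isC <- ctx$elem == "C"
  nC_nb <- vapply(seq_len(ctx$n), function(i) sum(ctx$A[i, ] > 0 & isC), numeric(1))
  for (i in which(isC)) {
    h <- ctx$hyb[i]; k <- nC_nb[i]
    nm <- paste0("C", k, "SP", h)
    if (nm %in% names(out)) out[nm] <- out[nm] + 1
  }
  out["FCSP3"] <- if (sum(isC) > 0) sum(isC & ctx$hyb == 3) / sum(isC) else NA_real_
  out
}

.constitutional_names <- function() {
  c(paste0("SAtom_", .WEIGHT_CODES), paste0("MAtom_", .WEIGHT_CODES))
}

.constitutional_compute <- function(ctx, aux) {
  nm <- .constitutional_names()
  out <- setNames(rep(NA_real_, length(nm)), nm)
  for (wc in .WEIGHT_CODES) {
    w <- ctx$W[, wc]
    if (any(is.na(w))) next
    ref <- if (wc %in% rownames(t(.ATOM_PROPS)) || wc %in% colnames(.ATOM_PROPS)) {
      .ATOM_PROPS["C", wc]
    } else {
      1
    }
    if (is.na(ref) || ref == 0) ref <- 1
    out[paste0("SAtom_", wc)] <- sum(w / ref)
    out[paste0("MAtom_", wc)] <- mean(w)
  }
  out
}

.MDE_CLASSES <- list(
  C = 1:4, O = 1:2, N = 1:3
)

.mde_names <- function() {
  nm <- character(0)
  for (e in names(.MDE_CLASSES)) {
    ks <- .MDE_CLASSES[[e]]
    for (k in ks) for (l in ks[ks >= k]) nm <- c(nm, paste0("MDE", e, k, l))
  }
  nm
}

.mde_compute <- function(ctx, aux) {
  nm <- .mde_names()
  out <- setNames(rep(0, length(nm)), nm)
  if (!ctx$connected) return(setNames(rep(NA_real_, length(nm)), nm))
  for (e in names(.MDE_CLASSES)) {
    for (k in .MDE_CLASSES[[e]]) {
      ak <- which(ctx$elem == e & ctx$deg == k)
      for (l in .MDE_CLASSES[[e]]) {
        if (l < k) next
        al <- which(ctx$elem == e & ctx$deg == l)
        if (k == l) {
          if (length(ak) < 2) next
          prs <- utils::combn(ak, 2)
          d <- ctx$D[cbind(prs[1, ], prs[2, ])]
        } else {
          if (length(ak) == 0 || length(al) == 0) next
          gr <- expand.grid(a = ak, b = al)
          gr <- gr[gr$a != gr$b, , drop = FALSE]
          if (nrow(gr) == 0) next
          d <- ctx$D[cbind(gr$a, gr$b)]
        }
        out[paste0("MDE", e, k, l)] <- length(d) / exp(mean(log(d)))
      }
    }
  }
  out
}

.topo_names <- function() {
  c(
    "WPath", "MeanWPath", "WPol", "Zagreb1", "Zagreb2", "mZagreb1",
    "mZagreb2", "BalabanJ", "BertzCT", "ECIndex", "TopoDiameter",
    "TopoRadius", "PetitjeanIndex", "ABCIndex"
  )
}

.topo_compute <- function(ctx, aux) {
  out <- setNames(rep(NA_real_, 14), .topo_names())
  n <- ctx$n
  d <- ctx$delta
  b <- ctx$bonds
  out["Zagreb1"] <- sum(d^2)
  out["mZagreb1"] <- sum(ifelse(d > 0, 1 / d^2, NA_real_))
  if (nrow(b)) {
    out["Zagreb2"] <- sum(d[b$i] * d[b$j])
    out["mZagreb2"] <- sum(1 / (d[b$i] * d[b$j]))
    out["ABCIndex"] <- sum(sqrt((d[b$i] + d[b$j] - 2) / (d[b$i] * d[b$j])))
    tot <- 2 * nrow(b)
    out["BertzCT"] <- tot * log2(tot) - sum(ifelse(d > 0, d * log2(d), 0))
  }
  if (ctx$connected && n > 1) {
    out["WPath"] <- sum(ctx$D) / 2
    out["MeanWPath"] <- out["WPath"] / choose(n, 2)
    out["WPol"] <- sum(ctx$D[upper.tri(ctx$D)] == 3)
    ecc <- apply(ctx$D, 1, max)
    out["ECIndex"] <- sum(ecc * d)
    out["TopoDiameter"] <- max(ecc)
    out["TopoRadius"] <- min(ecc)
    if (min(ecc) > 0) out["PetitjeanIndex"] <- (max(ecc) - min(ecc)) / min(ecc)
    if (nrow(b)) {
      s <- rowSums(ctx$D)
      mu <- nrow(b) - n + 1
      out["BalabanJ"] <- nrow(b) / (mu + 1) * sum(1 / sqrt(s[b$i] * s[b$j]))
    }
  }
  out
}

.physchem_names <- function() {
  c(
    "MW", "AMW", "SLogP", "SMR", "TopoPSA", "nHBAcc", "nHBDon",
    "McGowanV", "apol", "bpol"
  )
}

.physchem_compute <- function(ctx, aux) {
  out <- setNames(rep(NA_real_, 10), .physchem_names())
  pr <- aux$props
  if (!is.null(pr)) {
    out["MW"] <- pr$MW
    out["AMW"] <- pr$MW / (ctx$n + sum(ctx$nH))
    out["SLogP"] <- pr$logP
    out["SMR"] <- pr$MR
    out["TopoPSA"] <- pr$TPSA
    out["nHBAcc"] <- pr$HBA1
    out["nHBDon"] <- pr$HBD
  }
  mg <- atom_prop(ctx$elem, "mcgowan")
  if (!any(is.na(mg))) {
    nb_tot <- nrow(ctx$bonds) + sum(ctx$nH)
    out["McGowanV"] <- sum(mg) + sum(ctx$nH) * .ATOM_PROPS["H", "mcgowan"] -
      0.0656 * nb_tot
  }
  pol <- atom_prop(ctx$elem, "p")
  if (!any(is.na(pol))) {
    out["apol"] <- sum(pol) + sum(ctx$nH) * .ATOM_PROPS["H", "p"]
    if (nrow(ctx$bonds)) {
      out["bpol"] <- sum(abs(pol[ctx$bonds$i] - pol[ctx$bonds$j]))
    } else {
      out["bpol"] <- 0
    }
  }
  out
}

.PEOE_EDGES <- c(-Inf, -0.30, -0.25, -0.20, -0.15, -0.10, -0.05, 0,
  0.05, 0.10, 0.15, 0.20, 0.25, 0.30, Inf)
.ESTATE_VSA_EDGES <- c(-Inf, -0.39, 0.29, 0.717, 1.165, 1.54, 1.807, 2.05,
  4.69, 9.17, Inf)
.VSA_ESTATE_EDGES <- c(-Inf, 4.78, 5.00, 5.41, 5.74, 6.00, 6.07, 6.45,
  7.00, 11.0, Inf)

.COV_RADII <- c(
  H = 0.37, B = 0.84, C = 0.77, N = 0.75, O = 0.73, F = 0.71, Si = 1.11,
  P = 1.06, S = 1.02, Cl = 0.99, As = 1.19, Se = 1.17, Br = 1.14, I = 1.33
)

# Labute-style approximate per-atom van der Waals surface areas.
atom_vsa <- function(ctx) {
  R <- atom_prop(ctx$elem, "rvdw")
  rc <- .COV_RADII[ctx$elem]
  area <- 4 * pi * R^2
  cap <- function(Ri, Rj, dij) {
    h <- Ri - (Ri^2 + dij^2 - Rj^2) / (2 * dij)
    2 * pi * Ri * min(max(h, 0), 2 * Ri)
  }
  for (r in seq_len(nrow(ctx$bonds))) {
    i <- ctx$bonds$i[r]; j <- ctx$bonds$j[r]
    dij <- rc[i] + rc[j]
    area[i] <- area[i] - cap(R[i], R[j], dij)
    area[j] <- area[j] - cap(R[j], R[i], dij)
  }
  RH <- .ATOM_PROPS["H", "rvdw"]; rcH <- .COV_RADII[["H"]]
  for (i in seq_len(ctx$n)) {
    if (ctx$nH[i] > 0) {
      area[i] <- area[i] - ctx$nH[i] * cap(R[i], RH, rc[i] + rcH)
    }
  }
  pmax(area, 0)
}

.vsa_names <- function() {
  c(
    paste0("PEOE_VSA", 1:14), paste0("EState_VSA", 1:10),
    paste0("VSA_EState", 1:10)
  )
}

.vsa_compute <- function(ctx, aux) {
  nm <- .vsa_names()
  out <- setNames(rep(NA_real_, length(nm)), nm)
  vsa <- atom_vsa(ctx)
  if (any(is.na(vsa))) return(out)
  q <- ctx$q; S <- ctx$estate
  bin_sum <- function(value, by, edges) {
    idx <- findInterval(by, edges, rightmost.closed = FALSE)
    vapply(seq_len(length(edges) - 1), function(b) sum(value[idx == b]), numeric(1))
  }
  if (!any(is.na(q))) {
    out[paste0("PEOE_VSA", 1:14)] <- bin_sum(vsa, q, .PEOE_EDGES)
  }
  if (all(is.finite(S))) {
    out[paste0("EState_VSA", 1:10)] <- bin_sum(vsa, S, .ESTATE_VSA_EDGES)
    out[paste0("VSA_EState", 1:10)] <- bin_sum(S, vsa, .VSA_ESTATE_EDGES)
  }
  out
}

# Family registry: names are static, compute operates per molecule.
.desc_families <- function() {
  list(
    autocorrelation = list(names = .autocorr_names(), compute = .autocorr_compute),
    spectral = list(names = .spectral_names(), compute = .spectral_compute),
    chi = list(names = .chi_names(), compute = .chi_compute),
    kappa = list(names = .kappa_names(), compute = .kappa_compute),
    pathcount = list(names = .pathcount_names(), compute = .pathcount_compute),
    walkcount = list(names = .walk_names(), compute = .walk_compute),
    infocontent = list(names = .ic_names(), compute = .ic_compute),
    estate = list(names = .estate_names(), compute = .estate_compute),
    ringcount = list(names = .ringcount_names(), compute = .ringcount_compute),
    atomcount = list(names = .atomcount_names(), compute = .atomcount_compute),
    bondcount = list(names = .bondcount_names(), compute = .bondcount_compute),
    carbontype = list(names = .carbontype_names(), compute = .carbontype_compute),
    constitutional = list(names = .constitutional_names(), compute = .constitutional_compute),
    mde = list(names = .mde_names(), compute = .mde_compute),
    topology = list(names = .topo_names(), compute = .topo_compute),
    physchem = list(names = .physchem_names(), compute = .physchem_compute),
    vsa = list(names = .vsa_names(), compute = .vsa_compute)
  )
}
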