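# Shared graph enumeration helpers for the topological descriptor families.

# Aggregate simple-path statistics up to length `lmax` edges.
# For each length h returns: count, sum over paths of prod(delta)^-1/2,
# same with valence delta, and sum of products of bond orders (pi-path).
path_stats <- function(ctx, lmax = 10L) {
  n <- ctx$n
  out <- list(
    count = numeric(lmax), chi = numeric(lmax),
    chiv = numeric(lmax), pic = numeric(lmax)
  )
  if (n < 2 || nrow(ctx$bonds) == 0) return(out)
  adj <- lapply(seq_len(n), function(i) which(ctx$A[i, ] > 0))
  B <- matrix(0, n, n)
  B[cbind(ctx$bonds$i, ctx$bonds$j)] <- ctx$bonds$order
  B[cbind(ctx$bonds$j, ctx$bonds$i)] <- ctx$bonds$order
  d <- ctx$delta; dv <- ctx$deltav
  sd_ <- ifelse(d > 0, 1 / sqrt(d), NA_real_)
  sdv <- ifelse(dv > 0, 1 / sqrt(dv), NA_real_)
  visited <- logical(n)
  dfs <- function(v, start, h, w_chi, w_chiv, w_pi) {
    for (u in adj[[v]]) {
      if (visited[u]) next
      nw_chi <- w_chi * sd_[u]; nw_chiv <- w_chiv * sdv[u]
      nw_pi <- w_pi * B[v, u]
      if (u > start) {   # count undirected paths once
        out$count[h] <<- out$count[h] + 1
        out$chi[h] <<- out$chi[h] + nw_chi
        out$chiv[h] <<- out$chiv[h] + nw_chiv
        out$pic[h] <<- out$pic[h] + nw_pi
      }
      if (h < lmax) {
        visited[u] <<- TRUE
        dfs(u, start, h + 1L, nw_chi, nw_chiv, nw_pi)
        visited[u] <<- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    visited[s] <- TRUE
    dfs(s, s, 1L, sd_[s], sdv[s], 1)
    visited[s] <- FALSE
  }
  out
}

# Ring (chain) chi sums for cycle sizes 3..smax: sum over distinct cycles of
# prod(delta)^-1/2 (simple and valence).
cycle_stats <- function(ctx, smax = 7L) {
  n <- ctx$n
  out <- list(chi = numeric(smax), chiv = numeric(smax), count = numeric(smax))
  if (n < 3 || nrow(ctx$bonds) == 0) return(out)
  adj <- lapply(seq_len(n), function(i) which(ctx$A[i, ] > 0))
  d <- ctx$delta; dv <- ctx$deltav
  sd_ <- ifelse(d > 0, 1 / sqrt(d), NA_real_)
  sdv <- ifelse(dv > 0, 1 / sqrt(dv), NA_real_)
  visited <- logical(n)
  path <- integer(smax + 1L)
  dfs <- function(v, start, h, w, wv) {
    for (u in adj[[v]]) {
      if (u == start && h >= 3) {
        # close the cycle; avoid direction double-count: second < last vertex
        if (path[2] < v) {
          out$count[h] <<- out$count[h] + 1
          out$chi[h] <<- out$chi[h] + w
          out$chiv[h] <<- out$chiv[h] + wv
        }
      } else if (!visited[u] && u > start && h < smax) {
        visited[u] <<- TRUE
        path[h + 1L] <<- u
        dfs(u, start, h + 1L, w * sd_[u], wv * sdv[u])
        visited[u] <<- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    visited[s] <- TRUE
    path[1] <- s
    dfs(s, s, 1L, sd_[s], sdv[s])
    visited[s] <- FALSE
  }
  out
}

# Atoms that belong to at least one ring (incident to a non-bridge edge).
ring_atoms <- function(ctx) {
  n <- ctx$n
  inring <- logical(n)
  if (nrow(ctx$bonds) == 0) return(inring)
  br <- igraph::bridges(ctx$ig)
  el <- igraph::as_edgelist(ctx$ig)
  nonbridge <- setdiff(seq_len(nrow(el)), as.integer(br))
  for (e in nonbridge) {
    inring[el[e, 1]] <- TRUE; inring[el[e, 2]] <- TRUE
  }
  inring
}

# Eigen-based descriptor suite over a symmetric matrix.
spectral_suite <- function(M, ctx, suffix) {
  nm <- paste0(
    c(
      "SpAbs", "SpMax", "SpDiam", "SpAD", "SpMAD", "LogEE", "SM1",
      "VE1", "VE2", "VE3", "VR1", "VR2", "VR3"
    ),
    "_", suffix
  )
  n <- ctx$n
  res <- setNames(rep(NA_real_, 13), nm)
  if (is.null(M) || any(!is.finite(M))) return(res)
  eg <- eigen(M, symmetric = TRUE)
  ev <- eg$values
  res[1] <- sum(abs(ev))
  res[2] <- max(ev)
  res[3] <- max(ev) - min(ev)
  res[4] <- sum(abs(ev - mean(ev)))
  res[5] <- res[4] / n
  mx <- max(ev)
  res[6] <- mx + log(sum(exp(ev - mx)))  # log-sum-exp
  res[7] <- sum(ev)
  v1 <- abs(eg$vectors[, 1])
  ve1 <- sum(v1)
  res[8] <- ve1
  res[9] <- ve1 / n
  if (ve1 > 0) res[10] <- log(0.1 * n * ve1)
  if (nrow(ctx$bonds) > 0) {
    pr <- v1[ctx$bonds$i] * v1[ctx$bonds$j]
    if (all(pr > 0)) {
      vr1 <- sum(pr^(-0.5))
      res[11] <- vr1
      res[12] <- vr1 / n
      res[13] <- log(0.1 * n * vr1)
    }
  }
  res
}

# Barysz weighted distance matrix for a tabulated atomic property.
barysz_matrix <- function(ctx, code) {
  if (!ctx$connected) return(NULL)
  w <- ctx$W[, code]
  wc <- .ATOM_PROPS["C", code]
  if (any(is.na(w)) || any(w == 0)) return(NULL)
  n <- ctx$n
  if (n == 1) return(matrix(1 - wc / w, 1, 1))
  ew <- (wc * wc) / (w[ctx$bonds$i] * w[ctx$bonds$j] * ctx$bonds$order)
  g <- igraph::graph_from_edgelist(cbind(ctx$bonds$i, ctx$bonds$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  M <- igraph::distances(g, weights = ew)
  diag(M) <- 1 - wc / w
  M
}

# Burden connectivity matrix with a property-loaded diagonal.
burden_matrix <- function(ctx, code) {
  w <- ctx$W[, code]
  if (any(is.na(w))) return(NULL)
  n <- ctx$n
  M <- matrix(0.001, n, n)
  if (nrow(ctx$bonds)) {
    bo <- ctx$bonds$order / 10
    M[cbind(ctx$bonds$i, ctx$bonds$j)] <- bo
    M[cbind(ctx$bonds$j, ctx$bonds$i)] <- bo
  }
  diag(M) <- w
  M
}
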