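# Molecular graph backend.
#
# Structure perception (SMILES parsing, aromaticity, hybridization, Gasteiger
# charges) is delegated to OpenBabel; this file parses its mol2 output into a
# plain heavy-atom graph context consumed by the descriptor families.

# Parse concatenated mol2 text into a list of raw molecule blocks.
parse_mol2 <- function(lines) {
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0) return(list())
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(b) {
    blk <- lines[starts[b]:ends[b]]
    title <- trimws(blk[2])
    sec <- function(name) {
      i <- grep(paste0("^@<TRIPOS>", name, "$"), blk)
      if (length(i) == 0) return(character(0))
      j <- grep("^@<TRIPOS>", blk)
      nxt <- j[j > i[1]]
      end <- if (length(nxt)) nxt[1] - 1L else length(blk)
      blk[(i[1] + 1L):end]
    }
    atom_lines <- sec("ATOM")
    bond_lines <- sec("BOND")
    attr_lines <- sec("UNITY_ATOM_ATTR")
    atoms <- do.call(rbind, lapply(atom_lines, function(l) {
      f <- strsplit(trimws(l), "\\s+")[[1]]
      data.frame(
        id = as.integer(f[1]), sybyl = f[6],
        charge = as.numeric(f[9]), stringsAsFactors = FALSE
      )
    }))
    bonds <- if (length(bond_lines)) {
      do.call(rbind, lapply(bond_lines, function(l) {
        f <- strsplit(trimws(l), "\\s+")[[1]]
        data.frame(
          a1 = as.integer(f[2]), a2 = as.integer(f[3]),
          type = f[4], stringsAsFactors = FALSE
        )
      }))
    } else {
      data.frame(a1 = integer(0), a2 = integer(0), type = character(0))
    }
    # formal charges: "<atom_id> <n_attr>" header lines followed by attr lines
    fq <- numeric(nrow(atoms))
    i <- 1L
    while (i < length(attr_lines)) {
      hd <- strsplit(trimws(attr_lines[i]), "\\s+")[[1]]
      aid <- as.integer(hd[1]); nat <- as.integer(hd[2])
      for (k in seq_len(nat)) {
        av <- strsplit(trimws(attr_lines[i + k]), "\\s+")[[1]]
        if (av[1] == "charge") fq[aid] <- as.numeric(av[2])
      }
      i <- i + 1L + nat
    }
    atoms$fcharge <- fq
    list(title = title, atoms = atoms, bonds = bonds)
  })
}

.sybyl_elem <- function(sybyl) sub("\\..*$", "", sybyl)

.bond_order_num <- function(type) {
  switch(type, "1" = 1, "2" = 2, "3" = 3, "ar" = 1.5, "am" = 1, 1)
}

# Build the heavy-atom graph context for one parsed mol2 block.
build_mol_context <- function(raw) {
  elem_all <- .sybyl_elem(raw$atoms$sybyl)
  heavy <- which(elem_all != "H")
  n <- length(heavy)
  if (n == 0) return(NULL)
  remap <- rep(NA_integer_, nrow(raw$atoms))
  remap[heavy] <- seq_len(n)

  elem <- elem_all[heavy]
  q <- raw$atoms$charge[heavy]
  fq <- raw$atoms$fcharge[heavy]
  sybyl <- raw$atoms$sybyl[heavy]

  nH <- integer(n)
  hb <- raw$bonds
  keep <- logical(nrow(hb))
  for (r in seq_len(nrow(hb))) {
    e1 <- elem_all[hb$a1[r]]; e2 <- elem_all[hb$a2[r]]
    if (e1 == "H" && e2 != "H") {
      nH[remap[hb$a2[r]]] <- nH[remap[hb$a2[r]]] + 1L
    } else if (e2 == "H" && e1 != "H") {
      nH[remap[hb$a1[r]]] <- nH[remap[hb$a1[r]]] + 1L
    } else if (e1 != "H" && e2 != "H") {
      keep[r] <- TRUE
    }
  }
  bonds <- hb[keep, , drop = FALSE]
  bonds$i <- remap[bonds$a1]; bonds$j <- remap[bonds$a2]
  bonds$order <- vapply(bonds$type, .bond_order_num, numeric(1))
  bonds$arom <- bonds$type == "ar"

  A <- matrix(0, n, n)
  if (nrow(bonds)) {
    A[cbind(bonds$i, bonds$j)] <- 1
    A[cbind(bonds$j, bonds$i)] <- 1
  }
  deg <- rowSums(A)
  arom <- grepl("\\.ar$", sybyl)
  if (nrow(bonds)) {
    for (r in which(bonds$arom)) {
      arom[bonds$i[r]] <- TRUE; arom[bonds$j[r]] <- TRUE
    }
  }
  hyb <- ifelse(grepl("\\.1$", sybyl), 1L,
    ifelse(grepl("\\.(2|ar|am|pl3|co2|cat)$", sybyl), 2L, 3L)
  )
  hyb[arom] <- 2L

  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  D <- igraph::distances(ig)
  connected <- all(is.finite(D))

  Z <- atom_prop(elem, "Z"); Zv <- atom_prop(elem, "Zv")
  L <- atom_prop(elem, "L")
  deltav <- (Zv - nH) / (Z - Zv - 1)
  istate <- ifelse(deg > 0, ((2 / L)^2 * deltav + 1) / deg, NA_real_)
  # Kier-Hall E-state: intrinsic state plus field perturbation over distance
  estate <- istate
  if (n > 1 && connected && all(is.finite(istate))) {
    for (ii in seq_len(n)) {
      dij <- D[ii, -ii]
      estate[ii] <- istate[ii] + sum((istate[ii] - istate[-ii]) / (dij + 1)^2)
    }
  }

  W <- matrix(NA_real_, n, length(.WEIGHT_CODES),
    dimnames = list(NULL, .WEIGHT_CODES)
  )
  W[, "c"] <- q
  W[, "dv"] <- deltav
  W[, "d"] <- deg
  W[, "s"] <- istate
  for (code in c("Z", "m", "v", "se", "pe", "are", "p", "i")) {
    W[, code] <- atom_prop(elem, code)
  }

  list(
    n = n, elem = elem, nH = nH, q = q, fq = fq, sybyl = sybyl,
    arom = arom, hyb = hyb, deg = deg, bonds = bonds, A = A, ig = ig,
    D = D, connected = connected, delta = deg, deltav = deltav,
    istate = istate, estate = estate, W = W
  )
}

#' Build molecular graph contexts for a vector of SMILES
#'
#' Runs OpenBabel once over all molecules (explicit hydrogens, Gasteiger
#' charges) and parses the resulting mol2 into heavy-atom graph contexts.
#'
#' @param smiles character vector of standardized SMILES
#' @return list of graph contexts (NULL where OpenBabel failed to parse)
#' @keywords internal
mol_graphs <- function(smiles) {
  if (length(smiles) == 0) return(list())
  tags <- paste0("TKMOL", seq_along(smiles))
  input <- paste(smiles, tags)
  out <- run_obabel(input, c("-ismi", "-omol2", "-h", "-e", "--partialcharge", "gasteiger"))
  raws <- parse_mol2(out)
  by_tag <- setNames(raws, vapply(raws, `[[`, "", "title"))
  lapply(tags, function(t) {
    r <- by_tag[[t]]
    if (is.null(r)) NULL else build_mol_context(r)
  })
}
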