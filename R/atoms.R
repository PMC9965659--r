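# Atom featurization: 10 descriptor blocks concatenated into one fixed-width
# numeric vector per heavy atom. One-hot vocabularies are frozen at build
# time; everything else is a scalar.

.ATOM_SYMBOLS <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb", "W"
)

.HYBRIDIZATIONS <- c("SP", "SP2", "SP3", "SP3D", "SP3D2", "other")
.CHIRALITY <- c("unspecified", "CW", "CCW", "other")

.ATOMIC_NUMBER <- c(
  H = 1, Li = 3, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12,
  Al = 13, Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Ti = 22,
  V = 23, Cr = 24, Mn = 25, Fe = 26, Co = 27, Ni = 28, Cu = 29, Zn = 30,
  Ge = 32, As = 33, Se = 34, Br = 35, Zr = 40, Pd = 46, Ag = 47, Cd = 48,
  In = 49, Sn = 50, Sb = 51, I = 53, W = 74, Pt = 78, Au = 79, Hg = 80,
  Tl = 81, Pb = 82, Yb = 70
)

#' Atom descriptor schema
#'
#' Ordered list of the 10 atom descriptor blocks used to featurize heavy
#' atoms: atom symbol (one-hot over a 44-symbol vocabulary plus an "other"
#' slot), atomic number (scalar), hybridization (one-hot over SP/SP2/SP3/
#' SP3D/SP3D2/other), number of adjacent heavy atoms (scalar), chirality
#' (one-hot over unspecified/CW/CCW/other), formal charge (scalar),
#' aromaticity (0/1), number of bonded hydrogens (scalar), explicit valence
#' (scalar), implicit valence (scalar). Block widths sum to the package-wide
#' node feature dimension returned by [atom_feature_dim()].
#'
#' @return A list of blocks, each with `name`, `kind` ("onehot" or
#'   "scalar"), `levels` (for one-hot blocks) and `width`.
#' @export
atom_schema <- function() {
  blocks <- list(
    list(name = "symbol", kind = "onehot",
         levels = c(.ATOM_SYMBOLS, "other")),
    list(name = "atomic_number", kind = "scalar"),
    list(name = "hybridization", kind = "onehot", levels = .HYBRIDIZATIONS),
    list(name = "degree", kind = "scalar"),
    list(name = "chirality", kind = "onehot", levels = .CHIRALITY),
    list(name = "formal_charge", kind = "scalar"),
    list(name = "aromatic", kind = "scalar"),
    list(name = "num_h", kind = "scalar"),
    list(name = "explicit_valence", kind = "scalar"),
    list(name = "implicit_valence", kind = "scalar")
  )
  lapply(blocks, function(b) {
    b$width <- if (b$kind == "onehot") length(b$levels) else 1L
    b
  })
}

#' @rdname atom_schema
#' @export
atom_feature_dim <- function(schema = atom_schema()) {
  sum(vapply(schema, `[[`, integer(1), "width"))
}

#' Featurize a single atom record
#'
#' Concatenates the 10 descriptor blocks of [atom_schema()] in schema order.
#' An atom symbol outside the vocabulary is routed to the reserved "other"
#' slot, never dropped.
#'
#' @param atom A list (or one-row data frame) with fields `symbol`,
#'   `atomic_number`, `hybridization`, `degree`, `chirality`,
#'   `formal_charge`, `aromatic`, `num_h`, `explicit_valence`,
#'   `implicit_valence`.
#' @param schema Descriptor schema, default [atom_schema()].
#' @return Numeric vector of length [atom_feature_dim()].
#' @export
featurize_atom <- function(atom, schema = atom_schema()) {
  needed <- vapply(schema, `[[`, character(1), "name")
  missing <- setdiff(needed, names(atom))
  if (length(missing) > 0) {
    stop("atom record missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(schema, function(b) {
    v <- atom[[b$name]]
    if (b$kind == "scalar") return(as.numeric(v))
    hot <- numeric(b$width)
    i <- match(as.character(v), b$levels)
    if (is.na(i)) i <- match("other", b$levels)
    if (is.na(i)) i <- b$width
    hot[i] <- 1
    hot
  })
  unlist(out, use.names = FALSE)
}

.sdf_charge <- function(code) {
  # SDF atom-block charge codes: 1..7 = +3,+2,+1,doublet,-1,-2,-3
  map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
           `6` = -2, `7` = -3)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0
  unname(out)
}

.default_valence <- function(symbol, charge, explicit) {
  base <- switch(symbol,
    B = 3, C = 4, N = 3, O = 2, F = 1, Cl = 1, Br = 1, I = 1,
    P = c(3, 5), S = c(2, 4, 6), Si = 4, Se = c(2, 4, 6), As = c(3, 5),
    0)
  target <- if (symbol == "C") base - abs(charge) else base + charge
  target <- target[target >= explicit]
  if (length(target) == 0) return(explicit)
  min(target)
}

.hybridization_of <- function(aromatic, n_double, n_triple, steric) {
  if (steric >= 6) return("SP3D2")
  if (steric == 5) return("SP3D")
  if (n_triple > 0 || n_double >= 2) return("SP")
  if (aromatic || n_double == 1) return("SP2")
  "SP3"
}

#' Convert a SMILES string to a molecular graph
#'
#' Parses the SMILES with OpenBabel (via \pkg{ChemmineR}) into a heavy-atom
#' graph: one node per non-hydrogen atom (hydrogens implicit), one
#' undirected edge per bond (stored once; expand with
#' [graph_edges_directed()]). Node features follow [atom_schema()].
#' Aromaticity comes from ring perception; hybridization, hydrogen counts
#' and implicit valences are derived from bond orders, formal charges and
#' standard valence rules. Atom order follows appearance order in the
#' SMILES string.
#'
#' @param smiles A single non-empty SMILES string.
#' @param schema Descriptor schema, default [atom_schema()].
#' @return A `molecular_graph`: list with `features` (atoms x
#'   [atom_feature_dim()] matrix), `edges` (two-column matrix of 1-based
#'   atom indices, one row per bond), `atoms` (tibble of raw descriptors),
#'   `coords` (2D depiction coordinates) and `smiles`.
#' @examples
#' g <- smiles_to_graph("CCO")
#' nrow(g$features)  # 3 heavy atoms
#' nrow(g$edges)     # 2 bonds
#' @export
smiles_to_graph <- function(smiles, schema = atom_schema()) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (!nzchar(smiles)) stop("empty SMILES", call. = FALSE)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))),
    error = function(e) NULL)
  if (is.null(sdf) || length(sdf) == 0) {
    stop("unparseable SMILES: ", smiles, call. = FALSE)
  }
  .sdf_to_graph(sdf[[1]], smiles, schema)
}

#' Convert many SMILES to graphs in one OpenBabel call
#'
#' @param smiles Character vector of SMILES strings.
#' @inheritParams smiles_to_graph
#' @return List of `molecular_graph` objects (same order as input).
#' @export
smiles_to_graphs <- function(smiles, schema = atom_schema()) {
  stopifnot(is.character(smiles), all(nzchar(smiles)))
  uniq <- unique(smiles)
  names(uniq) <- paste0("m", seq_along(uniq))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(uniq)),
    error = function(e) stop("unparseable SMILES in batch: ",
                             conditionMessage(e), call. = FALSE))
  if (length(sdf) != length(uniq)) {
    stop("SMILES batch parse dropped molecules", call. = FALSE)
  }
  graphs <- lapply(seq_along(uniq), function(i) {
    .sdf_to_graph(sdf[[i]], uniq[[i]], schema)
  })
  graphs[match(smiles, uniq)]
}

.sdf_to_graph <- function(mol, smiles, schema) {
  ab <- ChemmineR::atomblock(mol)
  n <- nrow(ab)
  if (is.null(n) || n == 0) stop("unparseable SMILES: ", smiles, call. = FALSE)
  symbols <- sub("_[0-9]+$", "", rownames(ab))
  if (n == 1 && symbols[1] == "0") {
    # single-atom molecules round-trip through the SDF reader as a dummy
    # block; recover symbol and charge from the SMILES itself
    m <- regmatches(smiles,
                    regexec("^\\[?([A-Z][a-z]?)H?[0-9]?([+-][0-9]?)?\\]?$",
                            smiles))[[1]]
    if (length(m) == 0) stop("unparseable SMILES: ", smiles, call. = FALSE)
    chg <- if (m[3] == "") 0 else {
      sgn <- if (substr(m[3], 1, 1) == "-") -1 else 1
      mag <- if (nchar(m[3]) > 1) as.integer(substr(m[3], 2, 2)) else 1
      sgn * mag
    }
    implicit <- max(0, .default_valence(m[2], chg, 0))
    atoms <- tibble::tibble(
      symbol = m[2],
      atomic_number = unname(ifelse(is.na(.ATOMIC_NUMBER[m[2]]), 0,
                                    .ATOMIC_NUMBER[m[2]])),
      hybridization = "SP3", degree = 0, chirality = "unspecified",
      formal_charge = chg, aromatic = 0, num_h = implicit,
      explicit_valence = 0, implicit_valence = implicit)
    feats <- matrix(featurize_atom(as.list(atoms[1, ]), schema), nrow = 1)
    return(structure(list(features = feats,
                          edges = matrix(integer(0), ncol = 2),
                          atoms = atoms, coords = matrix(0, 1, 2),
                          smiles = smiles),
                     class = "molecular_graph"))
  }
  heavy <- which(symbols != "H")
  if (length(heavy) == 0) stop("no heavy atoms in SMILES: ", smiles, call. = FALSE)
  remap <- rep(NA_integer_, n)
  remap[heavy] <- seq_along(heavy)

  nh <- length(heavy)
  bb <- ChemmineR::bondblock(mol)
  edges <- matrix(integer(0), ncol = 2)
  orders <- numeric(0)
  h_explicit <- numeric(nh)   # explicit [H] neighbours folded into num_h
  if (!is.null(bb) && NROW(bb) > 0 && NCOL(bb) >= 3) {
    bb <- bb[bb[, 1] > 0 & bb[, 2] > 0, , drop = FALSE]  # drop dummy rows
  }
  if (!is.null(bb) && NROW(bb) > 0 && NCOL(bb) >= 3) {
    a1 <- as.integer(bb[, 1]); a2 <- as.integer(bb[, 2])
    ord <- as.numeric(bb[, 3])
    keep <- !is.na(remap[a1]) & !is.na(remap[a2])
    edges <- cbind(remap[a1[keep]], remap[a2[keep]])
    orders <- ord[keep]
    toH <- xor(is.na(remap[a1]), is.na(remap[a2]))
    if (any(toH)) {
      hv <- ifelse(is.na(remap[a1[toH]]), remap[a2[toH]], remap[a1[toH]])
      for (v in hv) h_explicit[v] <- h_explicit[v] + 1
    }
  }

  # aromatic atoms: ring perception from the toolkit, then a Hueckel-style
  # test on the kekulized bond orders (every ring atom either carries a ring
  # double bond, contributing 1 pi electron, or is a N/O/S heteroatom
  # contributing a lone pair; 4n + 2 total)
  aromatic <- rep(FALSE, nh)
  ring_list <- tryCatch(
    suppressWarnings(ChemmineR::rings(mol, type = "all", arom = FALSE)),
    error = function(e) NULL)
  if (!is.null(ring_list) && length(ring_list) > 0 && nrow(edges) > 0) {
    has_ring_double <- rep(FALSE, nh)
    ring_atoms_all <- unique(unlist(lapply(ring_list, function(r)
      remap[as.integer(sub(".*_", "", r))]), use.names = FALSE))
    ring_atoms_all <- ring_atoms_all[!is.na(ring_atoms_all)]
    for (r in seq_len(nrow(edges))) {
      if (orders[r] == 2 && all(edges[r, ] %in% ring_atoms_all)) {
        has_ring_double[edges[r, ]] <- TRUE
      }
    }
    for (ring in ring_list) {
      idx <- remap[as.integer(sub(".*_", "", ring))]
      idx <- idx[!is.na(idx)]
      if (length(idx) < 5 || length(idx) > 6) next
      sym <- symbols[heavy][idx]
      hetero <- sym %in% c("N", "O", "S") & !has_ring_double[idx]
      participates <- has_ring_double[idx] | hetero
      if (!all(participates)) next
      pi_e <- sum(has_ring_double[idx]) + 2 * sum(hetero)
      if (pi_e %% 4 == 2) aromatic[idx] <- TRUE
    }
  }

  charge <- if ("C6" %in% colnames(ab)) .sdf_charge(ab[, "C6"])[heavy]
            else rep(0, nh)
  parity <- if ("C7" %in% colnames(ab)) as.integer(ab[heavy, "C7"]) else rep(0L, nh)
  chirality <- .CHIRALITY[ifelse(parity == 1, 2L, ifelse(parity == 2, 3L,
                          ifelse(parity == 0, 1L, 4L)))]

  degree <- n_double <- n_triple <- explicit <- numeric(nh)
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      for (endp in 1:2) {
        v <- edges[r, endp]
        degree[v] <- degree[v] + 1
        explicit[v] <- explicit[v] + orders[r]
        if (orders[r] == 2) n_double[v] <- n_double[v] + 1
        if (orders[r] == 3) n_triple[v] <- n_triple[v] + 1
      }
    }
  }
  sym_h <- symbols[heavy]
  implicit_h <- vapply(seq_len(nh), function(i) {
    max(0, .default_valence(sym_h[i], charge[i], explicit[i] + h_explicit[i]) -
          explicit[i] - h_explicit[i])
  }, numeric(1))
  num_h <- implicit_h + h_explicit
  hyb <- vapply(seq_len(nh), function(i) {
    .hybridization_of(aromatic[i], n_double[i], n_triple[i],
                      degree[i] + num_h[i])
  }, character(1))

  atoms <- tibble::tibble(
    symbol = sym_h,
    atomic_number = unname(ifelse(is.na(.ATOMIC_NUMBER[sym_h]), 0,
                                  .ATOMIC_NUMBER[sym_h])),
    hybridization = hyb,
    degree = degree,
    chirality = chirality,
    formal_charge = charge,
    aromatic = as.numeric(aromatic),
    num_h = num_h,
    explicit_valence = explicit + h_explicit,
    implicit_valence = implicit_h
  )
  feats <- t(vapply(seq_len(nh), function(i) {
    featurize_atom(as.list(atoms[i, ]), schema)
  }, numeric(atom_feature_dim(schema))))

  structure(list(
    features = feats,
    edges = edges,
    atoms = atoms,
    coords = unname(ab[heavy, c("C1", "C2"), drop = FALSE]),
    smiles = smiles
  ), class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph: %d atoms, %d bonds, %s>\n",
              nrow(x$features), nrow(x$edges), x$smiles))
  invisible(x)
}

#' Expand the undirected bond list to both directions
#'
#' @param graph A `molecular_graph`.
#' @return Two-column integer matrix with each bond present in both
#'   directions (2 x bonds rows).
#' @export
graph_edges_directed <- function(graph) {
  e <- graph$edges
  if (nrow(e) == 0) return(matrix(integer(0), ncol = 2))
  rbind(e, e[, 2:1, drop = FALSE])
}
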