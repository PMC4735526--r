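# Structural comparison utilities for PDB coordinate files: Kabsch
# superposition RMSD, Shrake-Rupley solvent-accessible surface area
# (SASA), buried dimer interface area, and RNA end-to-end distances.
#
# Parsing policy (bit-reproducible defaults): model 1 only, alternate
# locations resolved by keeping blank or 'A', waters excluded.

.default_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
.water_resids <- c("HOH", "WAT", "DOD", "H2O")
.backbone_atoms <- c("N", "CA", "C", "O")

#' Read a PDB coordinate file
#'
#' Parses ATOM and HETATM records of model 1, resolves alternate
#' locations by keeping blank or \code{'A'}, and drops waters by default.
#'
#' @param path PDB file.
#' @param keep_waters retain water molecules (default \code{FALSE}).
#' @return An object of class \code{structure_model}: list with
#'   \code{atoms} (data frame: \code{type}, \code{chain}, \code{resno},
#'   \code{insert}, \code{resid}, \code{elety}, \code{element}, \code{x},
#'   \code{y}, \code{z}) and \code{accession} (file stem).
#' @export
read_pdb <- function(path, keep_waters = FALSE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse PDB ", path, ": ",
                         conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("no ATOM/HETATM records in ", path)
  alt <- at$alt
  keep <- is.na(alt) | alt == "" | alt == "A"
  at <- at[keep, , drop = FALSE]
  if (!keep_waters) at <- at[!(at$resid %in% .water_resids), , drop = FALSE]
  if (nrow(at) == 0L) stop("no usable atom records in ", path)
  element <- at$elesy
  missing_el <- is.na(element) | element == ""
  if (any(missing_el))
    element[missing_el] <- bio3d::atom2ele(at$elety[missing_el])
  atoms <- data.frame(type = at$type,
                      chain = ifelse(is.na(at$chain), "", at$chain),
                      resno = at$resno,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      resid = at$resid,
                      elety = at$elety,
                      element = toupper(element),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  structure(list(atoms = atoms,
                 accession = sub("\\.[^.]*$", "", basename(path))),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s': %d atoms, chains %s\n",
              x$accession, nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Describe an atom selection
#'
#' @param chains chain identifiers (in pairing order for superposition);
#'   \code{NULL} for all chains.
#' @param resno residue numbers to keep (a vector, e.g. \code{43:160});
#'   \code{NULL} for all.
#' @param atoms atom names to keep (e.g. \code{c("N","CA","C","O")});
#'   \code{NULL} for all.
#' @param protein_only restrict to ATOM records of amino-acid residues
#'   (default \code{FALSE}).
#' @return A list of class \code{atom_selection}.
#' @export
atom_selection <- function(chains = NULL, resno = NULL, atoms = NULL,
                           protein_only = FALSE) {
  structure(list(chains = chains, resno = resno, atoms = atoms,
                 protein_only = protein_only),
            class = "atom_selection")
}

#' Backbone selection helper (protein N, CA, C, O)
#' @inheritParams atom_selection
#' @return An \code{atom_selection} restricted to backbone atom names.
#' @export
backbone_selection <- function(chains = NULL, resno = NULL) {
  atom_selection(chains = chains, resno = resno, atoms = .backbone_atoms,
                 protein_only = TRUE)
}

#' Resolve an atom selection to row indices
#' @param model a \code{structure_model}.
#' @param sel an \code{\link{atom_selection}}.
#' @return Integer row indices into \code{model$atoms}.
#' @export
select_atoms <- function(model, sel) {
  stopifnot(inherits(model, "structure_model"),
            inherits(sel, "atom_selection"))
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chains)) keep <- keep & a$chain %in% sel$chains
  if (!is.null(sel$resno)) keep <- keep & a$resno %in% sel$resno
  if (!is.null(sel$atoms)) keep <- keep & a$elety %in% sel$atoms
  if (isTRUE(sel$protein_only))
    keep <- keep & a$type == "ATOM" &
      !(a$resid %in% c("A", "C", "G", "U", "DA", "DC", "DG", "DT", "DU"))
  which(keep)
}

# match selected atoms of two structures by (paired chain, residue
# number + insertion, atom name); returns corresponding index vectors
.match_atoms <- function(mobile, target, sel_mobile, sel_target) {
  im <- select_atoms(mobile, sel_mobile)
  it <- select_atoms(target, sel_target)
  cm <- sel_mobile$chains %||% sort(unique(mobile$atoms$chain[im]))
  ct <- sel_target$chains %||% sort(unique(target$atoms$chain[it]))
  if (length(cm) != length(ct))
    stop("selections must pair equal numbers of chains (",
         length(cm), " vs ", length(ct), ")")
  key <- function(atoms, idx, chains) {
    ci <- match(atoms$chain[idx], chains)
    paste(ci, atoms$resno[idx], atoms$insert[idx], atoms$elety[idx],
          sep = "|")
  }
  km <- key(mobile$atoms, im, cm)
  kt <- key(target$atoms, it, ct)
  common <- intersect(km, kt)
  dropped <- length(km) + length(kt) - 2L * length(common)
  if (length(common) < 3L) {
    miss <- union(setdiff(km, kt), setdiff(kt, km))
    stop("fewer than 3 matched atoms; unmatched: ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  if (dropped > 0L)
    message(sprintf("superposition: %d unmatched atom(s) dropped", dropped))
  list(mobile = im[match(common, km)], target = it[match(common, kt)])
}

.kabsch <- function(X, Y) {
  # optimal proper rotation R and translation t minimizing |XR' + t - Y|
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
  H <- crossprod(Xc, Yc)            # t(Xc) %*% Yc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Yc)^2)))
  list(rotation = R, translation = yc - as.vector(xc %*% t(R)),
       rmsd = rmsd)
}

#' Optimal rigid superposition (Kabsch) and RMSD
#'
#' Least-squares rigid-body superposition of corresponding atoms,
#' constrained to a proper rotation (determinant +1).  Atoms are matched
#' by paired chain (i-th selected mobile chain onto i-th target chain),
#' residue number + insertion code, and atom name; only the intersection
#' of common atoms is used, with a message reporting any dropped atoms.
#'
#' @param mobile,target \code{structure_model}s.
#' @param sel_mobile,sel_target \code{\link{atom_selection}}s; default
#'   protein backbone (N, CA, C, O) of all chains.
#' @return A list of class \code{kabsch_fit}: \code{rotation} (3x3),
#'   \code{translation} (length 3), \code{rmsd} (Angstrom),
#'   \code{n_atoms}.  Applying \code{x %*% t(rotation) + translation}
#'   maps mobile coordinates onto the target frame.
#' @export
superpose_kabsch <- function(mobile, target,
                             sel_mobile = backbone_selection(),
                             sel_target = backbone_selection()) {
  m <- .match_atoms(mobile, target, sel_mobile, sel_target)
  X <- as.matrix(mobile$atoms[m$mobile, c("x", "y", "z")])
  Y <- as.matrix(target$atoms[m$target, c("x", "y", "z")])
  fit <- .kabsch(X, Y)
  structure(c(fit, list(n_atoms = nrow(X))), class = "kabsch_fit")
}

#' @export
print.kabsch_fit <- function(x, ...) {
  cat(sprintf("kabsch_fit: rmsd %.4f A over %d atoms\n",
              x$rmsd, x$n_atoms))
  invisible(x)
}

#' Backbone RMSD between two structures, minimizing over chain pairings
#'
#' For dimers the correspondence between the two chains of each structure
#' is ambiguous; both pairings are tried and the smaller RMSD is
#' reported along with the mapping used.
#'
#' @param mobile,target \code{structure_model}s.
#' @param chains_mobile,chains_target chain ids to compare (default: all
#'   protein chains, sorted).
#' @param resno optional residue-number filter applied to both.
#' @return A list: \code{rmsd}, \code{mapping} (named character vector,
#'   mobile chain -> target chain), \code{fit} (the winning
#'   \code{kabsch_fit}).
#' @export
backbone_rmsd <- function(mobile, target, chains_mobile = NULL,
                          chains_target = NULL, resno = NULL) {
  prot_chains <- function(model) {
    i <- select_atoms(model, backbone_selection())
    sort(unique(model$atoms$chain[i]))
  }
  if (is.null(chains_mobile)) chains_mobile <- prot_chains(mobile)
  if (is.null(chains_target)) chains_target <- prot_chains(target)
  stopifnot(length(chains_mobile) == length(chains_target))
  orders <- list(seq_along(chains_target))
  if (length(chains_target) == 2L) orders <- c(orders, list(2:1))
  best <- NULL
  for (o in orders) {
    fit <- tryCatch(superpose_kabsch(
      mobile, target,
      backbone_selection(chains = chains_mobile, resno = resno),
      backbone_selection(chains = chains_target[o], resno = resno)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$rmsd < best$fit$rmsd))
      best <- list(rmsd = fit$rmsd,
                   mapping = stats::setNames(chains_target[o],
                                             chains_mobile),
                   fit = fit)
  }
  if (is.null(best)) stop("no chain pairing produced a valid superposition")
  best
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA: test points are placed on each atom's solvent sphere
#' (van der Waals radius + probe radius) on a deterministic golden-spiral
#' lattice, and the accessible fraction is the share of points outside
#' every neighbouring atom's solvent sphere.
#'
#' @param model a \code{structure_model}.
#' @param indices atom row indices to include (default all); atoms outside
#'   the set are ignored entirely (they neither gain area nor occlude).
#' @param probe probe radius in Angstrom, default 1.4 (water).
#' @param sphere_points test points per atom, default 960.
#' @param radii named van der Waals radius table (Angstrom) by element;
#'   an element absent from the table is an error (no silent default).
#' @return Numeric vector of per-atom areas (Angstrom^2), one per
#'   included atom, with attribute \code{indices}; \code{sum()} gives the
#'   total.
#' @export
sasa <- function(model, indices = NULL, probe = 1.4,
                 sphere_points = 960L, radii = .default_radii) {
  stopifnot(inherits(model, "structure_model"), probe >= 0,
            sphere_points >= 12)
  a <- model$atoms
  if (is.null(indices)) indices <- seq_len(nrow(a))
  el <- a$element[indices]
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  xyz <- as.matrix(a[indices, c("x", "y", "z")])
  r <- unname(radii[el]) + probe
  n <- length(indices)
  unit <- .sphere_points(as.integer(sphere_points))
  areas <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < r[i] + r & seq_len(n) != i)
    if (length(nb) == 0L) {
      areas[i] <- 4 * pi * r[i]^2
      next
    }
    pts <- unit * r[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(pts))
    for (j in nb) {
      if (!any(acc)) break
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & d2 > r[j]^2
    }
    areas[i] <- 4 * pi * r[i]^2 * mean(acc)
  }
  attr(areas, "indices") <- indices
  areas
}

#' Buried interface area per monomer
#'
#' \code{(sasa(A alone) + sasa(B alone) - sasa(A and B together)) / 2}:
#' the solvent-accessible area each group loses upon complexation,
#' averaged over the two groups.  The selections decide which atoms
#' count: pass \code{protein_only = TRUE} selections to exclude nucleic
#' acids and heteroatoms, as done for protein-protein dimer interfaces.
#'
#' @param model a \code{structure_model}.
#' @param group_a,group_b disjoint \code{\link{atom_selection}}s.
#' @inheritParams sasa
#' @return Buried area per monomer (Angstrom^2), with attributes
#'   \code{sasa_a}, \code{sasa_b}, \code{sasa_complex} (totals).
#' @export
interface_area <- function(model, group_a, group_b, probe = 1.4,
                           sphere_points = 960L, radii = .default_radii) {
  ia <- select_atoms(model, group_a)
  ib <- select_atoms(model, group_b)
  if (length(intersect(ia, ib)))
    stop("group_a and group_b must be disjoint")
  if (length(ia) == 0L || length(ib) == 0L)
    stop("empty atom group")
  sa <- sum(sasa(model, ia, probe, sphere_points, radii))
  sb <- sum(sasa(model, ib, probe, sphere_points, radii))
  sab <- sum(sasa(model, c(ia, ib), probe, sphere_points, radii))
  out <- (sa + sb - sab) / 2
  attr(out, "sasa_a") <- sa
  attr(out, "sasa_b") <- sb
  attr(out, "sasa_complex") <- sab
  out
}

#' Distance between the RNA ends of two chains
#'
#' Euclidean distance from the 3'-terminal \code{O3'} atom of one RNA
#' chain to the 5'-terminal atom (\code{P} if present, else \code{O5'},
#' else \code{C5'}) of the other.  Both orderings are reported; in a
#' dimer that binds two RNAs in trans, spans well above the reach of a
#' short linker rule out a single contiguous RNA connecting the two
#' sites.
#'
#' @param model a \code{structure_model}.
#' @param chain_r1,chain_r2 distinct RNA chain ids.
#' @return Named numeric vector of length 2:
#'   \code{<r1>3p_to_<r2>5p} and \code{<r2>3p_to_<r1>5p} (Angstrom).
#' @export
rna_end_distance <- function(model, chain_r1, chain_r2) {
  stopifnot(inherits(model, "structure_model"))
  if (identical(chain_r1, chain_r2))
    stop("chain_r1 and chain_r2 must be distinct chains")
  a <- model$atoms
  end_atom <- function(chain, which_end) {
    ca <- a[a$chain == chain, , drop = FALSE]
    if (nrow(ca) == 0L) stop("chain ", chain, " not found")
    resnos <- sort(unique(ca$resno))
    rn <- if (which_end == "3p") max(resnos) else min(resnos)
    res <- ca[ca$resno == rn, , drop = FALSE]
    names_wanted <- if (which_end == "3p") "O3'" else c("P", "O5'", "C5'")
    for (nm in names_wanted) {
      hit <- which(res$elety == nm)
      if (length(hit)) return(unlist(res[hit[1], c("x", "y", "z")]))
    }
    stop(sprintf("chain %s residue %d lacks %s-terminal atom (%s)",
                 chain, rn, which_end, paste(names_wanted, collapse = "/")))
  }
  d <- function(p, q) sqrt(sum((p - q)^2))
  out <- c(d(end_atom(chain_r1, "3p"), end_atom(chain_r2, "5p")),
           d(end_atom(chain_r2, "3p"), end_atom(chain_r1, "5p")))
  names(out) <- c(sprintf("%s_3p_to_%s_5p", chain_r1, chain_r2),
                  sprintf("%s_3p_to_%s_5p", chain_r2, chain_r1))
  out
}
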