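#' Atomic model container
#'
#' A light wrapper around a data.frame of atoms (chain, residue number,
#' residue name, atom name, element, xyz in Angstrom, occupancy,
#' B factor, insertion code).  The (chain, resno, insert, elety) key is
#' unique; alternate locations must be resolved before construction.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`,
#'   `elety`, `elesy`, `x`, `y`, `z`, `o`, `b`, `insert`.
#' @return object of class `atomic_model`.
#' @export
atomic_model <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms needs columns: ", paste(need, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("coordinates must be finite")
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$elesy))
    atoms$elesy <- substr(trimws(atoms$elety), 1, 1)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key))
    stop("(chain, residue, insert, atom name) must be unique")
  structure(list(atoms = atoms), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<atomic_model> %d atoms, %d residues, chains: %s\n",
              nrow(a), length(unique(paste(a$chain, a$resno, a$insert))),
              paste(unique(a$chain), collapse = " ")))
  invisible(x)
}

#' Read an atomic model from PDB or mmCIF
#'
#' Parsing is delegated to bio3d; alternate locations are resolved to
#' the highest-occupancy conformer (ties to the first alphabetically)
#' and insertion codes are preserved in the residue key.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return an [atomic_model()].
#' @export
read_model <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif"
              else "pdb"
  pdb <- if (format == "cif") bio3d::read.cif(path)
         else bio3d::read.pdb(path, rm.alt = FALSE)
  a <- pdb$atom
  df <- data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                   elety = a$elety, elesy = a$elesy,
                   x = a$x, y = a$y, z = a$z,
                   o = ifelse(is.na(a$o), 1, a$o),
                   b = ifelse(is.na(a$b), 0, a$b),
                   insert = ifelse(is.na(a$insert), "", a$insert),
                   alt = ifelse(is.na(a$alt), "", a$alt),
                   stringsAsFactors = FALSE)
  df <- df[df$resid != "HOH", ]
  # altloc: keep the highest-occupancy conformer per atom key,
  # preserving the file order of the surviving atoms
  df$.ord <- seq_len(nrow(df))
  key <- paste(df$chain, df$resno, df$insert, df$elety)
  df <- df[order(key, -df$o, df$alt), ]
  df <- df[!duplicated(paste(df$chain, df$resno, df$insert, df$elety)), ]
  df <- df[order(df$.ord), ]
  df$alt <- NULL
  df$.ord <- NULL
  rownames(df) <- NULL
  atomic_model(df)
}

#' Write an atomic model as PDB
#'
#' Fixed-width ATOM records with coordinates at 3-decimal precision.
#'
#' @param model an [atomic_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  a <- model$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000,
    ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
    a$resid, a$chain, a$resno, ifelse(a$insert == "", " ", a$insert),
    a$x, a$y, a$z, a$o, a$b, a$elesy)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Residue selection expressions
#'
#' A selection is a union of chain:interval terms in the compact
#' syntax `"A:473-593+A:628-680"` (single residues as `"A:17"`).  The
#' myosin-head subdomain definitions used throughout are available
#' from [myosin_subdomains()].
#'
#' @param expr selection string.
#' @return object of class `residue_selection` (data.frame of `chain`,
#'   `start`, `end`).
#' @export
residue_selection <- function(expr) {
  if (inherits(expr, "residue_selection")) return(expr)
  terms <- strsplit(expr, "+", fixed = TRUE)[[1]]
  rows <- lapply(terms, function(t) {
    m <- regmatches(t, regexec("^([A-Za-z0-9]+):(-?\\d+)(?:-(-?\\d+))?$", t))[[1]]
    if (length(m) == 0) stop("cannot parse selection term: ", t)
    s <- as.integer(m[3])
    e <- if (m[4] == "") s else as.integer(m[4])
    if (e < s) stop("ill-ordered interval in: ", t)
    data.frame(chain = m[2], start = s, end = e)
  })
  structure(do.call(rbind, rows), class = c("residue_selection",
                                            "data.frame"))
}

select_atoms <- function(model, selection, elety = NULL,
                         chain_map = NULL) {
  sel <- residue_selection(selection)
  a <- model$atoms
  keep <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(sel))) {
    ch <- sel$chain[i]
    if (!is.null(chain_map) && ch %in% names(chain_map))
      ch <- chain_map[[ch]]
    keep <- keep | (a$chain == ch & a$resno >= sel$start[i] &
                      a$resno <= sel$end[i])
  }
  if (!is.null(elety)) keep <- keep & trimws(a$elety) %in% elety
  a[keep, , drop = FALSE]
}

#' Five-subdomain definition of the myosin head
#'
#' Heavy-chain residue ranges of the N-terminal 25 kDa domain (N25D:
#' 1-205), upper 50 kDa domain (U50D: 206-466 + 603-627), lower 50 kDa
#' domain (L50D: 467-602 + 628-680), converter domain (CD: 681-770)
#' and lever arm domain (LAD: 771-845).
#'
#' @param chain chain identifier holding the myosin heavy chain.
#' @return named list of selection strings.
#' @export
myosin_subdomains <- function(chain = "A") {
  list(
    N25D = sprintf("%s:1-205", chain),
    U50D = sprintf("%s:206-466+%s:603-627", chain, chain),
    L50D = sprintf("%s:467-602+%s:628-680", chain, chain),
    CD   = sprintf("%s:681-770", chain),
    LAD  = sprintf("%s:771-845", chain)
  )
}

## ---- rigid transforms and superposition ----

#' Rigid transform (proper rotation + translation)
#'
#' @param R 3 x 3 proper rotation matrix (det +1).
#' @param t length-3 translation, Angstrom.
#' @return object of class `rigid_transform` with derived rotation
#'   `angle_deg` in \[0, 180\] and unit `axis` (NA when the angle is
#'   negligible).
#' @export
rigid_transform <- function(R, t = c(0, 0, 0)) {
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("R must be orthonormal with determinant +1")
  tr <- sum(diag(R))
  angle <- acos(min(1, max(-1, (tr - 1) / 2))) * 180 / pi
  axis <- rotation_axis(R, angle)
  structure(list(R = R, t = as.numeric(t), angle_deg = angle,
                 axis = axis), class = "rigid_transform")
}

rotation_axis <- function(R, angle_deg) {
  if (angle_deg < 0.5) return(c(NA_real_, NA_real_, NA_real_))
  if (angle_deg < 179) {
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    return(v / sqrt(sum(v^2)))
  }
  # near 180 degrees: use the +1 eigenvector
  e <- eigen(R)
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sqrt(sum(v^2))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angle %.3f deg about (%s), |t| %.3f A\n",
              x$angle_deg,
              paste(sprintf("%.3f", x$axis), collapse = ", "),
              sqrt(sum(x$t^2))))
  invisible(x)
}

apply_transform <- function(xyz, tf) {
  sweep(xyz %*% t(tf$R), 2, -tf$t)
}

kabsch <- function(P, Q) {
  # optimal rotation/translation mapping P onto Q (n x 3 each)
  cp <- colMeans(P)
  cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp)
  Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cq - as.numeric(R %*% cp)
  list(R = R, t = t)
}

pair_ca <- function(mobile, target, selection, chain_map = NULL) {
  ma <- select_atoms(mobile, selection, elety = "CA",
                     chain_map = chain_map)
  ta <- select_atoms(target, selection, elety = "CA")
  key_m <- paste(ma$resno, ma$insert)
  key_t <- paste(ta$resno, ta$insert)
  common <- intersect(key_m, key_t)
  list(P = as.matrix(ma[match(common, key_m), c("x", "y", "z")]),
       Q = as.matrix(ta[match(common, key_t), c("x", "y", "z")]),
       n = length(common))
}

#' Least-squares rigid superposition over C-alpha atoms
#'
#' Pairs C-alpha atoms of the selection by residue number (via an
#' explicit chain mapping when the models use different chain ids) and
#' computes the optimal rigid transform (Kabsch) taking `mobile` onto
#' `target`, plus the post-fit RMSD.
#'
#' @param mobile,target [atomic_model()]s.
#' @param selection a [residue_selection()] or selection string
#'   (interpreted in `target` chain ids).
#' @param chain_map named list mapping selection chains to `mobile`
#'   chains (default: same ids).
#' @return list with `transform` (a [rigid_transform()]), `rmsd`
#'   (Angstrom), `n` (paired atoms).
#' @export
superpose <- function(mobile, target, selection, chain_map = NULL) {
  pr <- pair_ca(mobile, target, selection, chain_map)
  if (pr$n < 3) stop("fewer than 3 C-alpha pairs matched")
  # collinearity check on the target selection
  sv <- svd(sweep(pr$Q, 2, colMeans(pr$Q)))$d
  if (sv[2] < 1e-6 * max(sv[1], 1))
    stop("degenerate geometry: selection is collinear")
  kb <- kabsch(pr$P, pr$Q)
  moved <- sweep(pr$P %*% t(kb$R), 2, -kb$t)
  rmsd <- sqrt(mean(rowSums((moved - pr$Q)^2)))
  list(transform = rigid_transform(kb$R, kb$t), rmsd = rmsd, n = pr$n)
}

transform_model <- function(model, tf) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(tf$R)
  a$x <- xyz[, 1] + tf$t[1]
  a$y <- xyz[, 2] + tf$t[2]
  a$z <- xyz[, 3] + tf$t[3]
  atomic_model(a)
}

#' Per-domain C-alpha RMSD table
#'
#' Each domain is superposed independently (its own least-squares
#' frame) and its RMSD reported, matching the use of per-domain
#' deviations as a model-reliability measure.  Domains that cannot be
#' resolved in both models are skipped with a warning.
#'
#' @param model_a,model_b [atomic_model()]s.
#' @param domains named list of selection strings (e.g.
#'   [myosin_subdomains()]).
#' @param chain_map optional chain mapping for `model_a`.
#' @return data.frame with columns `domain`, `rmsd_A`, `n`.
#' @export
domain_rmsd_table <- function(model_a, model_b,
                              domains = myosin_subdomains(),
                              chain_map = NULL) {
  rows <- list()
  for (nm in names(domains)) {
    sp <- tryCatch(superpose(model_a, model_b, domains[[nm]], chain_map),
                   error = function(e) {
                     warning(sprintf("domain %s skipped: %s", nm,
                                     conditionMessage(e)))
                     NULL
                   })
    if (is.null(sp)) next
    rows[[nm]] <- data.frame(domain = nm, rmsd_A = sp$rmsd, n = sp$n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Residual rigid rotation of a mobile domain after anchoring
#'
#' Superposes `model_b` onto `model_a` over the anchor selection, then
#' fits the residual rigid transform of the mobile selection.  Returns
#' the rotation angle (in \[0, 180\] degrees), the rotation axis, and
#' the axis tilt `acos(|axis . reference_axis|)` against a user-chosen
#' reference direction (the filament axis in filament work).  An angle
#' below 0.5 degrees reports an undefined (NA) axis.
#'
#' @param model_a,model_b [atomic_model()]s.
#' @param anchor,mobile selections (strings or
#'   [residue_selection()]s).
#' @param reference_axis length-3 vector (normalised internally).
#' @param chain_map optional chain mapping for `model_b`.
#' @return list with `angle_deg`, `axis`, `axis_tilt_deg`, and the
#'   anchor superposition `anchor_rmsd`.
#' @export
relative_domain_rotation <- function(model_a, model_b, anchor, mobile,
                                     reference_axis = c(0, 0, 1),
                                     chain_map = NULL) {
  sp_anchor <- superpose(model_b, model_a, anchor, chain_map)
  b_anchored <- transform_model(model_b, sp_anchor$transform)
  sp_mobile <- superpose(b_anchored, model_a, mobile, chain_map)
  tf <- sp_mobile$transform
  ref <- reference_axis / sqrt(sum(reference_axis^2))
  tilt <- if (any(is.na(tf$axis))) NA_real_
          else acos(min(1, abs(sum(tf$axis * ref)))) * 180 / pi
  list(angle_deg = tf$angle_deg, axis = tf$axis, axis_tilt_deg = tilt,
       anchor_rmsd = sp_anchor$rmsd, mobile_rmsd = sp_mobile$rmsd)
}

#' Rotate a domain of a model to build a ground-truth test pair
#'
#' Returns the model and a copy in which only the mobile selection is
#' rotated by `angle_deg` about `axis` through the selection's
#' C-alpha centroid, optionally with isotropic Gaussian coordinate
#' jitter applied to the whole copy.
#'
#' @param model an [atomic_model()].
#' @param mobile selection to rotate (non-empty).
#' @param angle_deg rotation angle, degrees.
#' @param axis length-3 rotation axis (non-zero).
#' @param jitter_sd_A per-coordinate Gaussian jitter, Angstrom.
#' @param seed RNG seed for the jitter.
#' @return list of two `atomic_model`s: `reference`, `rotated`.
#' @export
make_rotated_domain_pair <- function(model, mobile, angle_deg, axis,
                                     jitter_sd_A = 0, seed = 1) {
  if (sqrt(sum(axis^2)) == 0) stop("axis must be non-zero")
  sel <- select_atoms(model, mobile)
  if (nrow(sel) == 0) stop("empty mobile selection")
  R <- rotation_about_axis(axis, angle_deg)
  ca <- select_atoms(model, mobile, elety = "CA")
  ctr <- colMeans(as.matrix((if (nrow(ca)) ca else sel)[, c("x", "y", "z")]))
  a <- model$atoms
  sel_idx <- rownames(a) %in% rownames(sel)
  xyz <- as.matrix(a[sel_idx, c("x", "y", "z")])
  moved <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, -ctr)
  a[sel_idx, c("x", "y", "z")] <- moved
  if (jitter_sd_A > 0) {
    set.seed(seed)
    a$x <- a$x + rnorm(nrow(a), sd = jitter_sd_A)
    a$y <- a$y + rnorm(nrow(a), sd = jitter_sd_A)
    a$z <- a$z + rnorm(nrow(a), sd = jitter_sd_A)
  }
  list(reference = model, rotated = atomic_model(a))
}

#' Rotation matrix about an arbitrary axis
#' @param axis length-3 vector (normalised internally).
#' @param angle_deg rotation angle, degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

## ---- interface contacts ----

SB_POS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
               HIS = c("ND1", "NE2"))
SB_NEG <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BACKBONE <- c("N", "CA", "C", "O", "OXT")

#' List residue contact pairs across an interface
#'
#' All residue pairs between two disjoint groups whose minimum
#' any-atom distance is at or below the cutoff (inclusive), sorted by
#' distance.  With `classify = TRUE` each pair is classed as
#' `salt-bridge` (basic side-chain nitrogen within `sb_cutoff_A` of an
#' acidic side-chain oxygen), `hydrophobic` (side-chain carbon pair
#' within `hydro_cutoff_A`), or `other`.
#'
#' @param model an [atomic_model()].
#' @param group_a,group_b disjoint selections.
#' @param cutoff_A inclusive distance cutoff, Angstrom.
#' @param classify add a `class` column.
#' @param sb_cutoff_A,hydro_cutoff_A class-specific cutoffs.
#' @return data.frame: `residue_a`, `residue_b`, `min_dist_A`, `class`.
#' @export
contact_pairs <- function(model, group_a, group_b, cutoff_A = 4.5,
                          classify = TRUE, sb_cutoff_A = 4.0,
                          hydro_cutoff_A = 4.5) {
  aa <- select_atoms(model, group_a)
  ab <- select_atoms(model, group_b)
  if (nrow(aa) == 0 || nrow(ab) == 0) return(empty_contacts())
  key_a <- paste(aa$chain, aa$resno, aa$insert)
  key_b <- paste(ab$chain, ab$resno, ab$insert)
  if (length(intersect(unique(key_a), unique(key_b))))
    stop("groups must be disjoint")
  rows <- list()
  for (ra in unique(key_a)) {
    ia <- aa[key_a == ra, , drop = FALSE]
    xa <- as.matrix(ia[, c("x", "y", "z")])
    for (rb in unique(key_b)) {
      ib <- ab[key_b == rb, , drop = FALSE]
      xb <- as.matrix(ib[, c("x", "y", "z")])
      d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) -
        2 * xa %*% t(xb)
      dmin <- sqrt(max(0, min(d2)))
      if (dmin > cutoff_A) next
      cls <- if (classify) classify_contact(ia, ib, sb_cutoff_A,
                                            hydro_cutoff_A)
             else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        residue_a = sprintf("%s:%s%d", ia$chain[1], ia$resid[1],
                            ia$resno[1]),
        residue_b = sprintf("%s:%s%d", ib$chain[1], ib$resid[1],
                            ib$resno[1]),
        min_dist_A = dmin, class = cls)
    }
  }
  if (!length(rows)) return(empty_contacts())
  out <- do.call(rbind, rows)
  out[order(out$min_dist_A), , drop = FALSE]
}

empty_contacts <- function() {
  data.frame(residue_a = character(), residue_b = character(),
             min_dist_A = numeric(), class = character())
}

min_cross_dist <- function(xa, xb) {
  if (nrow(xa) == 0 || nrow(xb) == 0) return(Inf)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  sqrt(max(0, min(d2)))
}

classify_contact <- function(ia, ib, sb_cutoff_A, hydro_cutoff_A) {
  pick <- function(at, names_by_res) {
    res <- at$resid[1]
    if (!res %in% names(names_by_res)) return(at[0, , drop = FALSE])
    at[trimws(at$elety) %in% names_by_res[[res]], , drop = FALSE]
  }
  xyz <- function(at) as.matrix(at[, c("x", "y", "z")])
  # salt bridge in either direction
  d_sb <- min(min_cross_dist(xyz(pick(ia, SB_POS)), xyz(pick(ib, SB_NEG))),
              min_cross_dist(xyz(pick(ia, SB_NEG)), xyz(pick(ib, SB_POS))))
  if (d_sb <= sb_cutoff_A) return("salt-bridge")
  sc_carbon <- function(at)
    at[at$elesy == "C" & !trimws(at$elety) %in% BACKBONE, , drop = FALSE]
  d_h <- min_cross_dist(xyz(sc_carbon(ia)), xyz(sc_carbon(ib)))
  if (d_h <= hydro_cutoff_A) return("hydrophobic")
  "other"
}
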