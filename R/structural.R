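#' Coordinate trajectory
#'
#' Frames of atomic coordinates with per-atom metadata. Frames may come from
#' a multi-model PDB file ([read_pdb_trajectory()]), plain XYZ blocks with a
#' sidecar atom table ([read_xyz_frames()]) or a generator
#' ([gen_toy_trajectory()]).
#'
#' @param frames F x N x 3 array of coordinates (angstrom), or a list of
#'   N x 3 matrices.
#' @param atom_names per-atom names (e.g. `"CA"`); default all `"CA"`.
#' @param residue_ids per-atom 1-based residue identifiers.
#' @param chain_ids per-atom chain identifiers; default `"A"`.
#' @param time_step_ps time between frames (ps).
#' @return Object of class `"coord_trajectory"`.
#' @export
coord_trajectory <- function(frames, atom_names = NULL, residue_ids = NULL,
                             chain_ids = NULL, time_step_ps = 10) {
  if (is.list(frames)) {
    ns <- vapply(frames, nrow, integer(1L))
    if (length(unique(ns)) != 1L) stop("atom count must be constant across frames")
    frames <- aperm(simplify2array(frames), c(3L, 1L, 2L))
  }
  if (length(dim(frames)) != 3L || dim(frames)[3L] != 3L) {
    stop("frames must be an F x N x 3 array")
  }
  if (any(!is.finite(frames))) stop("coordinates must be finite")
  n_atoms <- dim(frames)[2L]
  if (is.null(atom_names)) atom_names <- rep("CA", n_atoms)
  if (is.null(residue_ids)) residue_ids <- seq_len(n_atoms)
  if (is.null(chain_ids)) chain_ids <- rep("A", n_atoms)
  stopifnot(length(atom_names) == n_atoms, length(residue_ids) == n_atoms,
            length(chain_ids) == n_atoms, time_step_ps > 0)
  structure(list(frames = frames, atom_names = as.character(atom_names),
                 residue_ids = as.integer(residue_ids),
                 chain_ids = as.character(chain_ids),
                 time_step_ps = as.numeric(time_step_ps)),
            class = "coord_trajectory")
}

#' @export
print.coord_trajectory <- function(x, ...) {
  cat(sprintf("Coordinate trajectory: %d frames x %d atoms @ %g ps\n",
              dim(x$frames)[1L], dim(x$frames)[2L], x$time_step_ps))
  invisible(x)
}

#' Alpha-carbon atom selection
#'
#' Indices of atoms named `"CA"`, optionally excluding residues (e.g. highly
#' flexible termini that would dominate an RMSD).
#'
#' @param traj a [coord_trajectory()].
#' @param exclude_residues residue ids to drop from the selection.
#' @return Integer vector of atom indices.
#' @export
ca_selection <- function(traj, exclude_residues = NULL) {
  stopifnot(inherits(traj, "coord_trajectory"))
  idx <- which(traj$atom_names == "CA")
  if (!is.null(exclude_residues)) {
    idx <- idx[!traj$residue_ids[idx] %in% exclude_residues]
  }
  idx
}

#' Kabsch superposition
#'
#' Least-squares optimal rigid superposition of one coordinate set onto a
#' reference via singular value decomposition of the cross-covariance
#' matrix, constrained to a proper rotation (determinant +1). Row-vector
#' convention: a point transforms as `x %*% rotation + translation`.
#'
#' @param mobile N x 3 matrix to superpose.
#' @param reference N x 3 matrix (same atom order).
#' @param selection optional atom indices used to compute the fit; the
#'   transformation is applied to all atoms.
#' @return List with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (angstrom, over the selection) and `coords` (transformed mobile set).
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference))
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3L) {
    stop("degenerate geometry: need at least 3 atoms for a superposition")
  }
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2L, ca); Bc <- sweep(B, 2L, cb)
  C <- crossprod(Ac, Bc)
  sv <- svd(C)
  if (sv$d[2L] <= 1e-10 * max(sv$d[1L], .Machine$double.eps)) {
    stop("degenerate geometry: selected atoms are (near-)collinear")
  }
  s <- sign(det(sv$u %*% t(sv$v)))
  if (s == 0) s <- 1
  rot <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  trans <- cb - ca %*% rot
  fitted_sel <- Ac %*% rot
  rmsd <- sqrt(mean(rowSums((fitted_sel - Bc)^2)))
  coords <- sweep(mobile, 2L, ca) %*% rot + rep(1, nrow(mobile)) %*% t(cb)
  list(rotation = rot, translation = as.numeric(trans), rmsd = rmsd,
       coords = coords)
}

#' Pairwise RMSD matrix
#'
#' Symmetric matrix of post-superposition RMSDs between every pair of
#' frames, computed on the alpha-carbon selection (optionally excluding
#' residues such as flexible termini).
#'
#' @param traj a [coord_trajectory()].
#' @param selection optional atom indices; defaults to the Calpha selection.
#' @param exclude_residues residue ids removed from the selection.
#' @return F x F numeric matrix (angstrom), zero diagonal.
#' @export
pairwise_rmsd <- function(traj, selection = NULL, exclude_residues = NULL) {
  stopifnot(inherits(traj, "coord_trajectory"))
  if (is.null(selection)) {
    selection <- ca_selection(traj, exclude_residues)
  } else if (!is.null(exclude_residues)) {
    selection <- selection[!traj$residue_ids[selection] %in% exclude_residues]
  }
  if (!length(selection)) stop("empty atom selection after exclusions")
  f <- dim(traj$frames)[1L]
  out <- matrix(0, f, f)
  if (f == 1L) return(out)
  sel_frames <- lapply(seq_len(f), function(i) {
    traj$frames[i, selection, , drop = TRUE]
  })
  for (i in seq_len(f - 1L)) {
    for (j in (i + 1L):f) {
      out[i, j] <- out[j, i] <-
        kabsch_superpose(sel_frames[[i]], sel_frames[[j]])$rmsd
    }
  }
  out
}

# k-means++ seeding: spread initial centers proportionally to squared
# distance from the nearest chosen center
.kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  ids <- integer(k)
  ids[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2L, X[ids[1L], ])^2)
  if (k > 1L) for (j in 2L:k) {
    if (all(d2 == 0)) {
      ids[j] <- sample.int(n, 1L)
    } else {
      ids[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[ids[j], ])^2))
  }
  X[ids, , drop = FALSE]
}

#' K-means conformational clustering
#'
#' K-means on a frame feature matrix (typically the rows of a pairwise RMSD
#' matrix), with k-means++ seeding, a fixed seed and multiple restarts so
#' that results are deterministic and well-converged.
#'
#' @param features frames x features numeric matrix (or a `"dist"`/square
#'   distance matrix, whose rows are then used as features).
#' @param k number of clusters, `1 <= k <= frames`.
#' @param seed RNG seed for the restarts (default 1).
#' @param nstart number of k-means++ restarts (default 10).
#' @param iter_max maximum Lloyd iterations per restart.
#' @return List with `labels`, `occupancy` data.frame (`cluster`, `n`,
#'   `occupancy_pct`), `tot_withinss` and `centers`.
#' @export
kmeans_cluster <- function(features, k, seed = 1, nstart = 10,
                           iter_max = 100) {
  if (inherits(features, "dist")) features <- as.matrix(features)
  X <- as.matrix(features)
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  if (k > nrow(X)) stop("k (", k, ") exceeds the number of frames (",
                        nrow(X), ")")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    centers <- .kmeanspp_centers(X, k)
    km <- suppressWarnings(
      stats::kmeans(X, centers = centers, iter.max = iter_max))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  ns <- tabulate(best$cluster, nbins = k)
  list(labels = best$cluster,
       occupancy = data.frame(cluster = seq_len(k), n = ns,
                              occupancy_pct = 100 * ns / nrow(X)),
       tot_withinss = best$tot.withinss,
       centers = best$centers)
}

#' Hierarchical agglomerative clustering with a distance cutoff
#'
#' Agglomerates frames from a pairwise distance matrix and stops merging
#' when the smallest inter-cluster linkage distance exceeds `epsilon`
#' (i.e. the tree is cut at height `epsilon`). Average linkage by default;
#' the original minimum-cluster-distance convention does not pin down the
#' linkage, so it is exposed as a choice.
#'
#' @param dist_matrix square symmetric distance matrix or `"dist"` object.
#' @param epsilon merge cutoff in the distance units (angstrom for RMSD).
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return List with `labels`, `occupancy` data.frame and the underlying
#'   `hclust` tree.
#' @export
hierarchical_cluster <- function(dist_matrix, epsilon,
                                 linkage = c("average", "single",
                                             "complete")) {
  linkage <- match.arg(linkage)
  d <- if (inherits(dist_matrix, "dist")) dist_matrix else
    stats::as.dist(as.matrix(dist_matrix))
  n <- attr(d, "Size")
  if (n < 2L) {
    labels <- rep(1L, n)
  } else {
    hc <- stats::hclust(d, method = linkage)
    labels <- stats::cutree(hc, h = epsilon)
  }
  ns <- tabulate(labels)
  list(labels = labels,
       occupancy = data.frame(cluster = seq_along(ns), n = ns,
                              occupancy_pct = 100 * ns / n),
       tree = if (n >= 2L) hc else NULL)
}

#' RMSF with a running-average reference
#'
#' Per-residue Calpha root-mean-square fluctuation computed against a
#' running-average reference: frames are first aligned to a common frame,
#' a centred moving average of the coordinates over `window_ps` is taken as
#' the local reference, each frame is re-fitted onto its own local
#' reference, and the RMSF of a residue is the root-mean-square deviation of
#' its Calpha from the windowed mean position. Using a local reference keeps
#' slow conformational drift out of the fluctuation measure. Windows are
#' truncated at the trajectory ends.
#'
#' @param traj a [coord_trajectory()].
#' @param window_ps running-average window (ps); default 10000 (10 ns).
#' @param selection optional atom indices; defaults to all Calpha atoms.
#' @param replicate_id,state optional metadata carried into the result.
#' @return Object of class `"rmsf_profile"`: data.frame with `residue_id`,
#'   `chain_id` and `rmsf` (angstrom).
#' @export
running_average_rmsf <- function(traj, window_ps = 10000, selection = NULL,
                                 replicate_id = "rep1", state = "reactant") {
  stopifnot(inherits(traj, "coord_trajectory"))
  if (is.null(selection)) selection <- ca_selection(traj)
  f <- dim(traj$frames)[1L]
  w <- max(2L, as.integer(round(window_ps / traj$time_step_ps)))
  if (w > f) stop("running-average window (", w,
                  " frames) exceeds trajectory length (", f, " frames)")
  # flatten the selected coordinates to an F x 3m matrix
  m <- length(selection)
  coords <- matrix(traj$frames[, selection, , drop = FALSE], nrow = f)
  to_mat <- function(row) matrix(row, ncol = 3L)

  # stage 1: remove global rigid motion by aligning every frame to frame 1
  ref1 <- to_mat(coords[1L, ])
  for (i in seq_len(f)) {
    coords[i, ] <- as.numeric(kabsch_superpose(to_mat(coords[i, ]), ref1)$coords)
  }

  # centred running mean, truncated at the edges
  half <- (w - 1L) %/% 2L
  cs <- rbind(0, apply(coords, 2L, cumsum))
  lo <- pmax(seq_len(f) - half, 1L)
  hi <- pmin(seq_len(f) + (w - 1L - half), f)
  runmean <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)

  # stage 2: fit each frame to its local reference and accumulate deviations
  sq <- matrix(0, f, m)
  for (i in seq_len(f)) {
    fit <- kabsch_superpose(to_mat(coords[i, ]), to_mat(runmean[i, ]))
    dev <- fit$coords - to_mat(runmean[i, ])
    sq[i, ] <- rowSums(dev^2)
  }
  rmsf <- sqrt(colMeans(sq))
  structure(data.frame(residue_id = traj$residue_ids[selection],
                       chain_id = traj$chain_ids[selection],
                       rmsf = rmsf),
            class = c("rmsf_profile", "data.frame"),
            replicate_id = replicate_id, state = state)
}

#' Per-residue two-state RMSF comparison
#'
#' Welch two-sample t-test per residue on replicate RMSF values from two
#' states, flagging residues whose flexibility differs at `p_threshold`
#' (default 0.01, matching the per-residue significance convention; no
#' multiple-testing correction by default, with a Benjamini-Hochberg option).
#' Residues with zero variance in both states get p = 1 when the means agree
#' and p = 0 otherwise.
#'
#' @param profiles_a,profiles_b replicate RMSF values for states A and B:
#'   either a list of [running_average_rmsf()] profiles or a residues x
#'   replicates numeric matrix. At least 2 replicates per state.
#' @param p_threshold significance threshold (default 0.01).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data.frame with `residue_id`, `mean_a`, `mean_b`, `p_value` and
#'   logical `significant`.
#' @export
rmsf_state_test <- function(profiles_a, profiles_b, p_threshold = 0.01,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  as_mat <- function(p) {
    if (is.matrix(p)) return(p)
    stopifnot(is.list(p), length(p) >= 1L)
    m <- vapply(p, function(x) x$rmsf, numeric(nrow(p[[1L]])))
    rownames(m) <- p[[1L]]$residue_id
    m
  }
  A <- as_mat(profiles_a); B <- as_mat(profiles_b)
  if (nrow(A) != nrow(B)) stop("states must cover the same residues")
  nA <- ncol(A); nB <- ncol(B)
  if (nA < 2L || nB < 2L) stop("need at least 2 replicates per state")
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- apply(A, 1L, stats::var); vB <- apply(B, 1L, stats::var)
  seA <- vA / nA; seB <- vB / nB
  se2 <- seA + seB
  tstat <- (mA - mB) / sqrt(se2)
  df <- se2^2 / (seA^2 / (nA - 1L) + seB^2 / (nB - 1L))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se2 == 0
  p[zero] <- ifelse(mA[zero] == mB[zero], 1, 0)
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  residues <- if (!is.null(rownames(A))) as.integer(rownames(A)) else
    seq_len(nrow(A))
  data.frame(residue_id = residues, mean_a = mA, mean_b = mB, p_value = p,
             significant = p < p_threshold, row.names = NULL)
}

#' Read a multi-model PDB file as a coordinate trajectory
#'
#' Uses bio3d to parse the models; all models must share the atom layout.
#'
#' @param path PDB file path.
#' @param time_step_ps time between models (ps).
#' @return A [coord_trajectory()].
#' @export
read_pdb_trajectory <- function(path, time_step_ps = 10) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  f <- nrow(xyz); n <- ncol(xyz) / 3L
  frames <- array(NA_real_, c(f, n, 3L))
  for (i in seq_len(f)) frames[i, , ] <- matrix(xyz[i, ], ncol = 3L,
                                                byrow = TRUE)
  coord_trajectory(frames, atom_names = pdb$atom$elety,
                   residue_ids = pdb$atom$resno,
                   chain_ids = pdb$atom$chain,
                   time_step_ps = time_step_ps)
}

#' Write a coordinate trajectory as a multi-model PDB file
#'
#' Minimal writer emitting MODEL/ATOM/ENDMDL records, enough for exchange
#' with standard structure tools.
#'
#' @param traj a [coord_trajectory()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pdb_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "coord_trajectory"))
  f <- dim(traj$frames)[1L]; n <- dim(traj$frames)[2L]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(f)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    for (a in seq_len(n)) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        a, substr(traj$atom_names[a], 1L, 4L), "ALA",
        substr(traj$chain_ids[a], 1L, 1L), traj$residue_ids[a],
        traj$frames[i, a, 1L], traj$frames[i, a, 2L],
        traj$frames[i, a, 3L]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read plain XYZ frames with a sidecar atom table
#'
#' The frame file holds whitespace-separated `x y z` lines, one atom per
#' line, frames concatenated; the atom table (comma or tab separated) has
#' columns `atom_name`, `residue_id`, `chain_id` and defines the atom count.
#'
#' @param path frames file.
#' @param atoms_path sidecar atom table.
#' @param time_step_ps time between frames (ps).
#' @return A [coord_trajectory()].
#' @export
read_xyz_frames <- function(path, atoms_path, time_step_ps = 10) {
  atoms <- .read_delim(atoms_path)
  need <- c("atom_name", "residue_id", "chain_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) {
    stop("atom table ", atoms_path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  raw <- as.matrix(utils::read.table(path, header = FALSE,
                                     comment.char = "#"))
  if (ncol(raw) != 3L) stop("XYZ file must have exactly 3 columns")
  n <- nrow(atoms)
  if (nrow(raw) %% n != 0L) {
    stop("XYZ row count is not a multiple of the atom count (", n, ")")
  }
  f <- nrow(raw) %/% n
  frames <- array(NA_real_, c(f, n, 3L))
  for (i in seq_len(f)) frames[i, , ] <- raw[((i - 1L) * n + 1L):(i * n), ]
  coord_trajectory(frames, atom_names = atoms$atom_name,
                   residue_ids = atoms$residue_id,
                   chain_ids = atoms$chain_id, time_step_ps = time_step_ps)
}

#' Write plain XYZ frames with a sidecar atom table
#'
#' @param traj a [coord_trajectory()].
#' @param path frames file to write.
#' @param atoms_path sidecar atom table to write.
#' @return Invisibly, `path`.
#' @export
write_xyz_frames <- function(traj, path, atoms_path) {
  stopifnot(inherits(traj, "coord_trajectory"))
  f <- dim(traj$frames)[1L]; n <- dim(traj$frames)[2L]
  block <- do.call(rbind, lapply(seq_len(f), function(i) {
    traj$frames[i, , , drop = TRUE]
  }))
  utils::write.table(format(block, digits = 10, trim = TRUE), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(atom_name = traj$atom_names, residue_id = traj$residue_ids,
               chain_id = traj$chain_ids),
    atoms_path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
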