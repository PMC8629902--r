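# Trajectory metrics: superposition, RMSD series, RMSF profiles,
# paired nonparametric comparison.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Expected number of frames for a sampled time span
#'
#' A span of `span_ns` nanoseconds sampled every `dt_ps` picoseconds,
#' inclusive of t = 0, yields `span/dt + 1` frames (10 ns at 2 ps = 5001).
#'
#' @param span_ns time span in ns (> 0).
#' @param dt_ps sampling interval in ps (> 0, must divide the span).
#' @return integer frame count.
#' @export
frame_count <- function(span_ns, dt_ps) {
  if (span_ns <= 0 || dt_ps <= 0)
    stop("span and dt must be positive", call. = FALSE)
  steps <- span_ns * 1000 / dt_ps
  if (abs(steps - round(steps)) > 1e-9)
    stop("span is not divisible by dt", call. = FALSE)
  as.integer(round(steps)) + 1L
}

#' Read a trajectory from a multi-model PDB file
#'
#' Every MODEL must carry the same atom roster (names and residue numbers in
#' the same order); a mismatch aborts with an error naming the offending
#' model. Frames are ordered by MODEL number; frame `i` (1-based) gets
#' timestamp `t0 + (i-1)*dt`.
#'
#' @param path multi-model PDB path (a file without MODEL records is read as
#'   a single frame).
#' @param dt time between frames, ps.
#' @param t0 time of the first frame, ps (default 0).
#' @return object of class `"zf_trajectory"`: list with `atoms` (roster
#'   data.frame: `elety`, `resid`, `resno`, `chain`), `xyz` (frames x 3N
#'   matrix), `dt`, `t0`, `times` (ps).
#' @export
read_trajectory <- function(path, dt = 2, t0 = 0) {
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts)) {
    bounds <- c(model_starts, length(lines) + 1L)
    rosters <- lapply(seq_along(model_starts), function(m) {
      blk <- lines[bounds[m]:(bounds[m + 1L] - 1L)]
      al <- blk[grepl("^(ATOM|HETATM)", blk)]
      paste(trimws(substr(al, 13, 16)), trimws(substr(al, 23, 26)))
    })
    for (m in seq_along(rosters)[-1])
      if (!identical(rosters[[m]], rosters[[1]]))
        stop("atom roster mismatch in model ", m, " of '", path, "'",
             call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  a <- pdb$atom
  atoms <- data.frame(elety = trimws(a$elety), resid = trimws(a$resid),
                      resno = a$resno, chain = a$chain,
                      stringsAsFactors = FALSE)
  nf <- nrow(xyz)
  structure(list(atoms = atoms, xyz = xyz, dt = dt, t0 = t0,
                 times = t0 + dt * (seq_len(nf) - 1L)),
            class = "zf_trajectory")
}

#' @export
print.zf_trajectory <- function(x, ...) {
  cat("<zf_trajectory> ", nrow(x$xyz), " frames x ", nrow(x$atoms),
      " atoms; dt = ", x$dt, " ps\n", sep = "")
  invisible(x)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a `"zf_trajectory"` (or a list with `atoms` and `xyz`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  a <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nrow(traj$xyz))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- matrix(traj$xyz[f, ], ncol = 3L, byrow = TRUE)
    name4 <- ifelse(nchar(a$elety) < 4L, sprintf(" %-3s", a$elety), a$elety)
    writeLines(sprintf(
      "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), name4, a$resid,
      ifelse(is.na(a$chain) | a$chain == "", "A", a$chain), a$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
      substr(a$elety, 1L, 1L)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid superposition of `mobile` onto `reference` with a
#' reflection guard: the returned rotation is proper (determinant +1).
#'
#' @param mobile,reference n x 3 coordinate matrices, paired by row (n >= 3
#'   non-collinear points).
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (minimum RMSD, Angstrom) and `fitted` (transformed mobile coordinates:
#'   `mobile %*% rotation + translation`).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("mobile and reference must be equal-size n x 3 matrices",
         call. = FALSE)
  if (nrow(mobile) < 3L)
    stop("at least 3 paired atoms are required", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  m0 <- sweep(mobile, 2, cm); r0 <- sweep(reference, 2, cr)
  if (min(svd(m0)$d) < 1e-12 && max(svd(m0)$d) > 0)
    warning("near-degenerate (collinear) geometry", call. = FALSE)
  h <- t(m0) %*% r0
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- sweep(m0 %*% t(rot), 2, cr, `+`)
  list(rotation = t(rot),
       translation = cr - as.numeric(cm %*% t(rot) %*% diag(3)),
       rmsd = rmsd_xyz(fitted, reference), fitted = fitted)
}

#' RMSD between two paired coordinate sets (no fitting)
#'
#' @param a,b n x 3 matrices paired by row.
#' @return root-mean-square deviation in Angstrom.
#' @export
rmsd_xyz <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  sqrt(mean(rowSums((a - b)^2)))
}

.selection_idx <- function(traj, selection) {
  if (is.numeric(selection)) return(as.integer(selection))
  if (identical(selection, "backbone"))
    return(which(traj$atoms$elety %in% BACKBONE_ATOMS))
  if (identical(selection, "all")) return(seq_len(nrow(traj$atoms)))
  stop("unknown selection", call. = FALSE)
}

.frame_coords <- function(traj, f, idx) {
  m <- matrix(traj$xyz[f, ], ncol = 3L, byrow = TRUE)
  m[idx, , drop = FALSE]
}

#' Per-frame RMSD after optimal superposition
#'
#' Each frame is independently superposed onto the reference over the
#' selection, then the RMSD over the same selection is recorded.
#'
#' @param traj a `"zf_trajectory"`.
#' @param reference frame index into `traj` (default 1) or an n x 3 matrix
#'   over the full atom roster.
#' @param selection `"backbone"` (default; atoms N, CA, C, O), `"all"`, or
#'   atom indices.
#' @return data.frame with `frame`, `time_ps`, `rmsd`; class `"rmsd_series"`.
#' @export
rmsd_series <- function(traj, reference = 1L, selection = "backbone") {
  idx <- .selection_idx(traj, selection)
  if (!length(idx)) stop("empty selection", call. = FALSE)
  ref <- if (is.matrix(reference)) reference[idx, , drop = FALSE]
         else .frame_coords(traj, reference, idx)
  vals <- vapply(seq_len(nrow(traj$xyz)), function(f) {
    superpose(.frame_coords(traj, f, idx), ref)$rmsd
  }, numeric(1))
  out <- data.frame(frame = seq_len(nrow(traj$xyz)), time_ps = traj$times,
                    rmsd = vals)
  class(out) <- c("rmsd_series", class(out))
  out
}

#' Per-residue RMSF profile
#'
#' Frames are superposed to an iterated mean structure (two passes: fit to
#' frame 1 and average, then re-fit to that mean and re-average); the RMSF
#' of residue r is the root of the mean squared deviation of its selected
#' atoms from their time-mean positions.
#'
#' @param traj a `"zf_trajectory"` with at least 2 frames.
#' @param selection as in [rmsd_series()].
#' @return data.frame with `resno` and `rmsf` (Angstrom); class
#'   `"rmsf_profile"`.
#' @export
rmsf_profile <- function(traj, selection = "backbone") {
  if (nrow(traj$xyz) < 2L)
    stop("RMSF needs at least 2 frames", call. = FALSE)
  idx <- .selection_idx(traj, selection)
  if (!length(idx)) stop("empty selection", call. = FALSE)
  nf <- nrow(traj$xyz)
  fit_all <- function(target) {
    arr <- array(NA_real_, c(nf, length(idx), 3L))
    for (f in seq_len(nf))
      arr[f, , ] <- superpose(.frame_coords(traj, f, idx), target)$fitted
    arr
  }
  arr <- fit_all(.frame_coords(traj, 1L, idx))
  mean1 <- apply(arr, c(2, 3), mean)
  arr <- fit_all(mean1)
  mean2 <- apply(arr, c(2, 3), mean)
  dev2 <- sweep(arr, c(2, 3), mean2)^2
  msf_atom <- apply(dev2, 2, mean) * 3  # mean over frames and coords, x3 => |r - rbar|^2
  resno <- traj$atoms$resno[idx]
  res <- unique(resno)
  rmsf <- vapply(res, function(r) sqrt(mean(msf_atom[resno == r])),
                 numeric(1))
  out <- data.frame(resno = res, rmsf = rmsf)
  class(out) <- c("rmsf_profile", class(out))
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided; zero differences are dropped. Exact null when at most
#' `exact_max` non-zero differences remain and there are no tied absolute
#' differences, otherwise the normal approximation with tie correction.
#' If every difference is zero the test is degenerate and `p = 1` by
#' convention.
#'
#' @param series_a,series_b equal-length numeric vectors paired by index.
#' @param exact_max largest n for the exact null distribution (default 25).
#' @return list with `W` (signed-rank statistic), `p_value`, `n_used`,
#'   `exact`.
#' @export
paired_wilcoxon <- function(series_a, series_b, exact_max = 25L) {
  if (length(series_a) != length(series_b))
    stop("series must be paired: lengths differ", call. = FALSE)
  d <- series_a - series_b
  d <- d[d != 0]
  if (!length(d))
    return(list(W = 0, p_value = 1, n_used = 0L, exact = TRUE,
                degenerate = TRUE))
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- length(d) <= exact_max && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = FALSE))
  list(W = unname(ht$statistic), p_value = ht$p.value,
       n_used = length(d), exact = exact, degenerate = FALSE)
}

#' Five-number summary of a series
#'
#' Quartiles use the linear-interpolation convention (R quantile type 7).
#'
#' @param series non-empty numeric vector.
#' @return list with `median`, `q1`, `q3`, `mean`, `sd`.
#' @export
series_summary <- function(series) {
  if (!length(series)) stop("empty series", call. = FALSE)
  q <- stats::quantile(series, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], mean = mean(series),
       sd = stats::sd(series))
}
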