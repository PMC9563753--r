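#' Read replicate MALDI peak lists from delimited text
#'
#' Expects a header with columns `sample_id`, `replicate_id`, `mz`,
#' `intensity` (tab- or comma-separated). Each (sample, replicate) pair
#' becomes one peak list; peaks are sorted by m/z at load time.
#'
#' @param path Path to the peak-list file.
#' @param sep Field separator; default `"\t"`.
#' @return Data frame of class `peak_data` with the four columns above,
#'   sorted by sample, replicate, m/z. A `replicates` attribute records the
#'   replicate count per sample.
#' @export
read_peak_lists <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("sample_id", "replicate_id", "mz", "intensity")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("peak-list file lacks column(s): ", paste(missing, collapse = ", "))
  df <- df[required]
  if (nrow(df) == 0L) {
    warning("peak-list file contains a header only")
  } else {
    if (!is.numeric(df$mz) || !is.numeric(df$intensity))
      stop("non-numeric mz or intensity values in peak-list file")
    if (any(df$intensity < 0)) stop("negative intensities in peak-list file")
    bad_rep <- !(df$replicate_id %in% 1:5)
    if (any(bad_rep))
      warning(sum(bad_rep), " row(s) with replicate_id outside 1..5 (kept)")
    df <- df[order(df$sample_id, df$replicate_id, df$mz), , drop = FALSE]
    rownames(df) <- NULL
  }
  reps <- if (nrow(df)) {
    u <- unique(df[c("sample_id", "replicate_id")])
    table(u$sample_id)
  } else table(character(0))
  attr(df, "replicates") <- reps
  class(df) <- c("peak_data", "data.frame")
  df
}

#' Assign observed peaks of one replicate spectrum to database lipids
#'
#' Each database entry takes the intensity of the observed peak with the
#' smallest absolute ppm deviation inside the tolerance window, or 0 when no
#' peak falls inside. When two entries' windows overlap on the same peak,
#' the nearer entry wins and the other falls back to its next-nearest
#' in-window candidate (or 0). Assignment depends only on m/z, never on
#' intensity, and is invariant to the input peak order.
#'
#' @param mz,intensity Numeric vectors of the replicate's peaks.
#' @param db An [build_database()] annotation database.
#' @param tolerance_ppm Matching window; defaults to the database's own.
#' @return Named numeric vector of intensities, one per database entry.
#' @export
assign_peaks <- function(mz, intensity, db,
                         tolerance_ppm = attr(db, "tolerance_ppm")) {
  stopifnot(length(mz) == length(intensity))
  n_db <- nrow(db)
  out <- stats::setNames(numeric(n_db), db$name)
  if (length(mz) == 0L) return(out)
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]

  # in-window candidates per entry, ranked by |dppm|
  cand <- lapply(seq_len(n_db), function(i) {
    dppm <- (mz - db$ion_mz[i]) / db$ion_mz[i] * 1e6
    hit <- which(abs(dppm) <= tolerance_ppm)
    hit[order(abs(dppm[hit]))]
  })
  # greedy resolution: repeatedly give each unsatisfied entry its best
  # remaining candidate; on conflict the entry with the smaller |dppm| keeps
  # the peak
  taken <- rep(NA_integer_, length(mz))   # peak -> entry holding it
  assigned <- rep(NA_integer_, n_db)      # entry -> peak
  pending <- which(lengths(cand) > 0L)
  while (length(pending)) {
    i <- pending[1L]; pending <- pending[-1L]
    repeat {
      if (!length(cand[[i]])) break
      p <- cand[[i]][1L]
      holder <- taken[p]
      if (is.na(holder)) {
        taken[p] <- i; assigned[i] <- p; break
      }
      d_new <- abs(mz[p] - db$ion_mz[i]) / db$ion_mz[i]
      d_old <- abs(mz[p] - db$ion_mz[holder]) / db$ion_mz[holder]
      if (d_new < d_old) {
        taken[p] <- i; assigned[i] <- p
        cand[[holder]] <- setdiff(cand[[holder]], p)
        assigned[holder] <- NA_integer_
        pending <- c(pending, holder)
        break
      }
      cand[[i]] <- cand[[i]][-1L]
    }
  }
  hit <- !is.na(assigned)
  out[hit] <- intensity[assigned[hit]]
  out
}

#' Aggregate replicate assignments into one per-sample intensity row
#'
#' Per lipid, the median across replicate depositions; unassigned replicates
#' count as 0 and an even replicate count takes the mean of the central pair.
#'
#' @param assignments Matrix (replicates x lipids) or list of named vectors
#'   from [assign_peaks()].
#' @return Named numeric vector of per-lipid median raw intensities.
#' @export
aggregate_replicates <- function(assignments) {
  if (is.list(assignments)) assignments <- do.call(rbind, assignments)
  if (is.null(dim(assignments))) assignments <- matrix(assignments, nrow = 1,
    dimnames = list(NULL, names(assignments)))
  if (nrow(assignments) == 0L) stop("zero replicates for sample")
  apply(assignments, 2, stats::median)
}

#' Build a samples-by-lipids intensity matrix from replicate peak lists
#'
#' Runs [assign_peaks()] per replicate spectrum and [aggregate_replicates()]
#' per sample. Samples with fewer than five replicates are accepted with a
#' warning.
#'
#' @param peaks A `peak_data` frame from [read_peak_lists()] (or any data
#'   frame with the same columns).
#' @param db Annotation database.
#' @param loq Limit of quantitation on raw intensity; stored for downstream
#'   filtering (default 8000, the lowest reproducible intensity).
#' @return An `intensity_matrix`: list with `intensity` (samples x lipids
#'   median raw intensities), `loq`, `is_channels`, and `class_map`
#'   (lipid name -> lipid class).
#' @export
peaks_to_matrix <- function(peaks, db, loq = 8000) {
  samples <- unique(peaks$sample_id)
  rows <- lapply(samples, function(s) {
    ps <- peaks[peaks$sample_id == s, , drop = FALSE]
    reps <- unique(ps$replicate_id)
    if (length(reps) < 5)
      warning("sample ", s, " has ", length(reps), " replicate(s), not 5")
    agg <- lapply(reps, function(r) {
      pr <- ps[ps$replicate_id == r, , drop = FALSE]
      assign_peaks(pr$mz, pr$intensity, db)
    })
    aggregate_replicates(agg)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- samples
  intensity_matrix(m, loq = loq,
                   is_channels = db$name[db$is_channel],
                   class_map = stats::setNames(quant_class(db$lipid_class),
                                               db$name))
}

#' Construct an intensity matrix container
#'
#' @param intensity Numeric samples x lipids matrix of median raw
#'   intensities (0 = unassigned).
#' @param loq Limit of quantitation (raw-intensity scale).
#' @param is_channels Character vector of internal-standard column names.
#' @param class_map Named character vector, lipid name -> lipid class.
#' @return Object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(intensity, loq = 8000,
                             is_channels = character(0),
                             class_map = NULL) {
  stopifnot(is.matrix(intensity), all(intensity >= 0))
  if (is.null(class_map))
    class_map <- stats::setNames(sub(" .*$", "", colnames(intensity)),
                                 colnames(intensity))
  structure(
    list(intensity = intensity, loq = loq,
         is_channels = intersect(is_channels, colnames(intensity)),
         class_map = class_map),
    class = "intensity_matrix"
  )
}

#' Below-LOQ mask of an intensity matrix
#' @param m An `intensity_matrix`.
#' @return Logical matrix, TRUE where the median raw intensity is below LOQ.
#' @export
loq_mask <- function(m) m$intensity < m$loq

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("intensity_matrix:", nrow(x$intensity), "samples x",
      ncol(x$intensity), "lipids; LOQ", x$loq, "\n")
  cat("  IS channels:", if (length(x$is_channels))
    paste(x$is_channels, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$intensity)

#' Write an intensity matrix (and its LOQ mask) as delimited text
#' @param m An `intensity_matrix`.
#' @param path Output path for the intensity table; the mask goes to
#'   `<path>.loqmask`.
#' @export
write_intensity_matrix <- function(m, path) {
  utils::write.table(data.frame(sample_id = rownames(m$intensity),
                                m$intensity, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(m$intensity),
                                loq_mask(m) * 1L, check.names = FALSE),
                     paste0(path, ".loqmask"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
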