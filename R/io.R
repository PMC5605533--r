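# Columnar text I/O for the pipeline's exchange formats.
#
# QENS spectra and elastic scans use Q-block files: lines "# Q = <value>"
# introduce a block of whitespace-separated rows (E I sigma, or T I sigma).
# SANS profiles are three-column (Q I sigma) and XRD patterns two- or
# three-column (2theta counts [sigma]) whitespace-delimited text with
# "#" comments. Trajectories are long tables (frame molecule x y z).
# Generator ground truth travels in a YAML sidecar.

write_q_blocks <- function(path, q, col1, mat, sig, header_cols, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(extra)) {
    for (nm in names(extra)) {
      writeLines(sprintf("# %s = %s", nm, format(extra[[nm]], digits = 15)), con)
    }
  }
  writeLines(paste0("# columns: ", paste(header_cols, collapse = " ")), con)
  for (j in seq_along(q)) {
    writeLines(sprintf("# Q = %.10g", q[j]), con)
    utils::write.table(
      data.frame(a = col1, b = mat[, j], c = sig[, j]),
      con, row.names = FALSE, col.names = FALSE, quote = FALSE
    )
  }
  invisible(path)
}

read_q_blocks <- function(path) {
  lines <- readLines(path)
  meta <- list()
  q <- numeric(0)
  blocks <- list()
  cur <- NULL
  flush_block <- function() {
    if (!is.null(cur) && length(cur)) {
      blocks[[length(blocks) + 1L]] <<- utils::read.table(text = cur)
    }
    cur <<- NULL
  }
  for (ln in lines) {
    if (grepl("^#", ln)) {
      m <- regmatches(ln, regexec("^#\\s*Q\\s*=\\s*([0-9.eE+-]+)", ln))[[1]]
      if (length(m) == 2) {
        flush_block()
        q <- c(q, as.numeric(m[2]))
        cur <- character(0)
      } else {
        kv <- regmatches(ln, regexec("^#\\s*([^=:]+)\\s*=\\s*(.+)$", ln))[[1]]
        if (length(kv) == 3) meta[[trimws(kv[2])]] <- trimws(kv[3])
      }
    } else if (nzchar(trimws(ln))) {
      cur <- c(cur, ln)
    }
  }
  flush_block()
  if (length(blocks) != length(q) || !length(q)) {
    stop("malformed Q-block file: ", path, call. = FALSE)
  }
  list(q = q, blocks = blocks, meta = meta)
}

#' Write / read a QENS spectrum in Q-block text format
#'
#' @param spectrum A `qens_spectrum`.
#' @param path Output file path.
#' @return `write_qens_spectrum` returns the path invisibly;
#'   `read_qens_spectrum` returns a `qens_spectrum`.
#' @export
write_qens_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "qens_spectrum"))
  write_q_blocks(path, spectrum$Q, spectrum$E, spectrum$I, spectrum$sigma,
                 c("E_ueV", "I", "sigma"),
                 extra = list(temperature_K = spectrum$temperature))
  invisible(path)
}

#' @rdname write_qens_spectrum
#' @export
read_qens_spectrum <- function(path) {
  parsed <- read_q_blocks(path)
  e <- parsed$blocks[[1]][[1]]
  intens <- vapply(parsed$blocks, function(b) b[[2]], numeric(length(e)))
  sig <- vapply(parsed$blocks, function(b) b[[3]], numeric(length(e)))
  temp <- as.numeric(parsed$meta[["temperature_K"]] %||% NA)
  structure(list(Q = parsed$q, E = e, I = intens, sigma = sig,
                 temperature = temp, truth = NULL),
            class = "qens_spectrum")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an elastic temperature scan in Q-block text format
#'
#' @param scan An `elastic_scan`.
#' @param path File path.
#' @return `write_elastic_scan` returns the path invisibly;
#'   `read_elastic_scan` an `elastic_scan`.
#' @export
write_elastic_scan <- function(scan, path) {
  stopifnot(inherits(scan, "elastic_scan"))
  write_q_blocks(path, scan$Q, scan$T, scan$I, scan$sigma,
                 c("T_K", "I_el", "sigma"))
  invisible(path)
}

#' @rdname write_elastic_scan
#' @export
read_elastic_scan <- function(path) {
  parsed <- read_q_blocks(path)
  tt <- parsed$blocks[[1]][[1]]
  intens <- vapply(parsed$blocks, function(b) b[[2]], numeric(length(tt)))
  sig <- vapply(parsed$blocks, function(b) b[[3]], numeric(length(tt)))
  structure(list(T = tt, Q = parsed$q, I = intens, sigma = sig, truth = NULL),
            class = "elastic_scan")
}

#' Write / read a SANS profile as three-column text (Q, I, sigma)
#'
#' @param profile A `sans_profile`.
#' @param path File path.
#' @param label Sample label on reading.
#' @return Path (write) or `sans_profile` (read).
#' @export
write_sans_profile <- function(profile, path) {
  stopifnot(inherits(profile, "sans_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# label = ", profile$label),
               "# columns: Q_invA I sigma"), con)
  utils::write.table(data.frame(profile$Q, profile$I, profile$sigma), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sans_profile
#' @export
read_sans_profile <- function(path, label = NULL) {
  lines <- readLines(path)
  lab <- "synthetic"
  m <- regmatches(lines, regexec("^#\\s*label\\s*=\\s*(\\S+)", lines))
  for (x in m) if (length(x) == 2) lab <- x[2]
  tab <- utils::read.table(text = lines[!grepl("^#", lines)])
  if (ncol(tab) < 3) stop("SANS profile needs 3 columns (Q, I, sigma)")
  structure(list(Q = tab[[1]], I = tab[[2]], sigma = tab[[3]],
                 label = label %||% lab, truth = NULL),
            class = "sans_profile")
}

#' Write / read an XRD pattern as columnar text (2theta, counts[, sigma])
#'
#' @param pattern An `xrd_pattern`.
#' @param path File path.
#' @param wavelength Wavelength (A) used when the file does not record one.
#' @return Path (write) or `xrd_pattern` (read).
#' @export
write_xrd_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "xrd_pattern"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# wavelength_A = %g", pattern$wavelength),
               "# columns: two_theta_deg counts sigma"), con)
  utils::write.table(data.frame(pattern$two_theta, pattern$counts,
                                pattern$sigma),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_xrd_pattern
#' @export
read_xrd_pattern <- function(path, wavelength = 1.542) {
  lines <- readLines(path)
  m <- regmatches(lines, regexec("^#\\s*wavelength_A\\s*=\\s*([0-9.eE+-]+)", lines))
  for (x in m) if (length(x) == 2) wavelength <- as.numeric(x[2])
  tab <- utils::read.table(text = lines[!grepl("^#", lines)])
  sig <- if (ncol(tab) >= 3) tab[[3]] else NULL
  structure(list(two_theta = tab[[1]], counts = tab[[2]], sigma = sig,
                 wavelength = wavelength, truth = NULL),
            class = "xrd_pattern")
}

#' Write / read water trajectories as a long table (frame molecule x y z)
#'
#' @param traj A `trajectory_set`.
#' @param path File path (tab-separated).
#' @return Path (write) or `trajectory_set` (read).
#' @export
write_trajectory_set <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  d <- dim(traj$positions)
  long <- data.frame(
    frame = rep(seq_len(d[1]), times = d[3]),
    molecule = rep(seq_len(d[3]), each = d[1]),
    x = as.vector(traj$positions[, 1, ]),
    y = as.vector(traj$positions[, 2, ]),
    z = as.vector(traj$positions[, 3, ])
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_interval_ps = %g", traj$frame_interval), con)
  writeLines(sprintf("# temperature_K = %g", traj$temperature), con)
  utils::write.table(long, con, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_trajectory_set
#' @export
read_trajectory_set <- function(path) {
  lines <- readLines(path)
  get_meta <- function(key, default) {
    m <- regmatches(lines, regexec(paste0("^#\\s*", key, "\\s*=\\s*([0-9.eE+-]+)"),
                                   lines))
    for (x in m) if (length(x) == 2) return(as.numeric(x[2]))
    default
  }
  dt <- get_meta("frame_interval_ps", 2)
  temp <- get_meta("temperature_K", NA_real_)
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE)
  mols <- sort(unique(tab$molecule))
  frames <- sort(unique(tab$frame))
  nf <- length(frames); nm <- length(mols)
  if (nrow(tab) != nf * nm) {
    stop("unequal frame counts per molecule", call. = FALSE)
  }
  tab <- tab[order(tab$molecule, tab$frame), ]
  pos <- array(NA_real_, dim = c(nf, 3L, nm))
  for (k in seq_len(nm)) {
    sl <- tab[((k - 1) * nf + 1):(k * nf), ]
    pos[, , k] <- as.matrix(sl[, c("x", "y", "z")])
  }
  structure(list(positions = pos, frame_interval = dt, temperature = temp,
                 D_true = NULL, component = NULL, truth = NULL),
            class = "trajectory_set")
}

#' Write generator ground truth as a YAML sidecar
#'
#' @param truth A ground-truth object or list from one of the generators.
#' @param path Output `.yaml` path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  clean <- rapply(unclass(truth), function(x) {
    if (is.data.frame(x)) as.list(x) else x
  }, how = "replace")
  yaml::write_yaml(clean, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  yaml::read_yaml(path)
}
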