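#' Read a HILLS file (PLUMED text dialect)
#'
#' Expects a `#! FIELDS ...` header naming the columns; comment lines
#' (starting with `#`) are skipped.  The bias factor is taken from a
#' `biasf` column if present, otherwise from a `#! SET biasf <value>`
#' header line.  Units follow the PLUMED text convention used throughout:
#' ps, angstrom, deg, kJ/mol.
#'
#' @param path file path.
#' @return A `hills` data frame with columns time, X, theta, sigma_X,
#'   sigma_theta, height, biasf, in time order.
#' @export
read_hills <- function(path) {
  parsed <- read_plumed_table(path,
    required = c("time", "X", "theta", "sigma_X", "sigma_theta", "height"))
  df <- parsed$data
  if (!"biasf" %in% names(df)) {
    if (is.na(parsed$set_biasf))
      stop("no 'biasf' column and no '#! SET biasf' header in ", path)
    df$biasf <- parsed$set_biasf
  }
  if (nrow(df) > 1 && any(diff(df$time) < 0))
    stop("non-monotone time in ", path, " at line ",
         parsed$lines[which(diff(df$time) < 0)[1] + 1])
  df <- df[c("time", "X", "theta", "sigma_X", "sigma_theta", "height",
             "biasf")]
  class(df) <- c("hills", "data.frame")
  df
}

#' Write a HILLS file
#'
#' @param hills a `hills` data frame (see [read_hills()]).
#' @param path output path.
#' @export
write_hills <- function(hills, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time X theta sigma_X sigma_theta height biasf", con)
  writeLines(sprintf("%.6f %.9f %.9f %.6f %.6f %.9f %.4f",
                     hills$time, hills$X, hills$theta, hills$sigma_X,
                     hills$sigma_theta, hills$height, hills$biasf), con)
  invisible(path)
}

#' Read a COLVAR file
#'
#' @param path file path.
#' @return A `biased_trajectory` data frame (time, X, theta, bias).
#' @export
read_colvar <- function(path) {
  parsed <- read_plumed_table(path,
    required = c("time", "X", "theta", "metad.bias"))
  df <- parsed$data[c("time", "X", "theta", "metad.bias")]
  names(df)[4] <- "bias"
  if (nrow(df) > 1 && any(diff(df$time) <= 0))
    stop("time not strictly increasing in ", path)
  class(df) <- c("biased_trajectory", "data.frame")
  df
}

#' Write a COLVAR file
#'
#' @param traj a `biased_trajectory` data frame.
#' @param path output path.
#' @export
write_colvar <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time X theta metad.bias", con)
  writeLines(sprintf("%.6f %.9f %.9f %.9f",
                     traj$time, traj$X, traj$theta, traj$bias), con)
  invisible(path)
}

# shared parser for the '#! FIELDS' table dialect
read_plumed_table <- function(path, required) {
  lines <- readLines(path)
  fields_i <- grep("^#!\\s*FIELDS", lines)
  if (length(fields_i) == 0)
    stop("no '#! FIELDS' header found in ", path)
  cols <- strsplit(sub("^#!\\s*FIELDS\\s+", "", lines[fields_i[1]]),
                   "\\s+")[[1]]
  # biasf may legitimately be absent from a HILLS header (SET line instead)
  hard_missing <- setdiff(setdiff(required, cols), "biasf")
  if (length(hard_missing) > 0)
    stop("missing column(s) in ", path, ": ",
         paste(hard_missing, collapse = ", "))
  set_biasf <- NA_real_
  set_i <- grep("^#!\\s*SET\\s+biasf\\s+", lines)
  if (length(set_i) > 0)
    set_biasf <- as.numeric(sub("^#!\\s*SET\\s+biasf\\s+", "", lines[set_i[1]]))
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  rows <- vector("list", length(data_idx))
  for (i in seq_along(data_idx)) {
    tok <- strsplit(trimws(lines[data_idx[i]]), "\\s+")[[1]]
    if (length(tok) != length(cols))
      stop("line ", data_idx[i], " of ", path, " has ", length(tok),
           " fields, expected ", length(cols))
    val <- suppressWarnings(as.numeric(tok))
    if (any(is.na(val)))
      stop("non-numeric value at line ", data_idx[i], " of ", path)
    rows[[i]] <- val
  }
  df <- as.data.frame(do.call(rbind, c(rows, list(matrix(numeric(0), 0,
                                                         length(cols))))))
  names(df) <- cols
  list(data = df, set_biasf = set_biasf, lines = data_idx)
}
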