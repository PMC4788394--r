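#' Read a numbered PNG/TIFF slice stack
#'
#' Loads all PNG or TIFF files in a directory as grayscale matrices, sorted
#' by the first integer appearing in each file name (slice order).  RGB(A)
#' images are collapsed to luminance by channel averaging; intensities are
#' rescaled to 0..255.
#'
#' @param dir directory containing the slice images.
#' @param pattern optional file-name regexp (default: PNG and TIFF
#'   extensions).
#' @return list of numeric matrices, one per slice, in slice order.
#' @export
read_image_stack <- function(dir, pattern = "\\.(png|tif|tiff)$") {
  if (!dir.exists(dir)) {
    stop("input directory does not exist: ", dir, call. = FALSE)
  }
  files <- list.files(dir, pattern = pattern, ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) {
    stop("no slice images found in ", dir, call. = FALSE)
  }
  nums <- as.integer(sub(".*?(\\d+).*", "\\1", basename(files)))
  if (anyNA(nums)) nums <- seq_along(files)
  files <- files[order(nums)]
  lapply(files, function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
      png::readPNG(f)
    } else {
      tiff::readTIFF(f)
    }
    if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE],
                                             c(1, 2), mean)
    img * 255
  })
}

#' Write boundary chains and corners of one slice as JSON
#'
#' Format: `{"units": ..., "slice": int, "chains": [{"closed": bool,
#' "chain": [[x, y], ...], "corners": [int, ...]}, ...]}`.
#'
#' @param path output path.
#' @param slice slice index.
#' @param chains list of chain matrices (see [trace_contours()]).
#' @param corners list of corner index vectors, one per chain.
#' @param units coordinate units recorded in the header (`"px"` or
#'   `"mm"`).
#' @return `path`, invisibly.
#' @export
write_chains_json <- function(path, slice, chains, corners = NULL,
                              units = "px") {
  entries <- lapply(seq_along(chains), function(i) {
    list(closed = isTRUE(attr(chains[[i]], "closed")),
         chain = unname(as.matrix(chains[[i]])[, 1:2, drop = FALSE]),
         corners = if (is.null(corners)) integer(0) else
           as.integer(corners[[i]]))
  })
  jsonlite::write_json(list(units = units, slice = as.integer(slice),
                            chains = entries),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read chains JSON written by [write_chains_json()]
#'
#' @param path JSON path.
#' @return list with `units`, `slice`, `chains` (matrices with `closed`
#'   attribute) and `corners` (integer vectors).
#' @export
read_chains_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  chains <- lapply(x$chains, function(ch) {
    m <- do.call(rbind, lapply(ch$chain, function(p) as.numeric(unlist(p))))
    colnames(m) <- c("x", "y")
    structure(m, closed = isTRUE(ch$closed))
  })
  corners <- lapply(x$chains, function(ch) as.integer(unlist(ch$corners)))
  list(units = x$units, slice = x$slice, chains = chains, corners = corners)
}

#' Write/read ordered contour points as CSV
#'
#' Plain CSV with columns `slice`, `contour`, `x`, `y` (one row per point,
#' in chain order).
#'
#' @param path CSV path.
#' @param chains_by_slice list (per slice) of lists of chain matrices.
#' @return for the writer, `path` invisibly; for the reader, the nested
#'   list of chain matrices.
#' @export
write_contours_csv <- function(path, chains_by_slice) {
  rows <- list()
  for (s in seq_along(chains_by_slice)) {
    for (k in seq_along(chains_by_slice[[s]])) {
      ch <- chains_by_slice[[s]][[k]]
      rows[[length(rows) + 1L]] <-
        data.frame(slice = s, contour = k, x = ch[, 1L], y = ch[, 2L])
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$slice), function(sl) {
    lapply(split(sl, sl$contour), function(ch) {
      cbind(x = ch$x, y = ch$y)
    })
  })
}

#' Read and write INI-style configuration files
#'
#' Minimal `[section]` / `key = value` text format used for GA and pipeline
#' settings, e.g. sections `[ga]` (population, generations, pc, pm, seed,
#' target_error) and `[bounds]` (a_max, b_max, lambda_max).  Values are
#' parsed as numbers where possible, else kept as strings.
#'
#' @param path file path.
#' @param config for the writer: a named list of named lists
#'   (section -> key -> value).
#' @return `read_config()` returns the nested list; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, ";")]
  out <- list()
  section <- "default"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      num <- suppressWarnings(as.numeric(val))
      out[[section]][[key]] <- if (!is.na(num)) num else val
    }
  }
  out
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  lines <- character(0)
  for (section in names(config)) {
    lines <- c(lines, sprintf("[%s]", section))
    sec <- config[[section]]
    for (key in names(sec)) {
      lines <- c(lines, sprintf("%s = %s", key, as.character(sec[[key]])))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}
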