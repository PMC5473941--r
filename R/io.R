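# File I/O: CSV tables, minimal STAR data tables, TIFF stacks, configs.

#' Write and read event/track tables
#'
#' Plain CSV round-trip for the tabular outputs of the simulators and
#' classifiers. Writers are thin [readr::write_csv()] wrappers kept so every
#' writer has a paired reader with declared columns.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return `write_table()` returns `path` invisibly; `read_table_csv()` the
#'   tibble.
#' @export
write_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read a particle class-assignment table (CSV or STAR)
#'
#' Ingests per-particle class assignments from either a CSV file or a
#' minimal STAR data table (a single `data_` block with a `loop_`). Column
#' names are mapped via `mapping` (e.g. `c(micrograph_id =
#' "rlnMicrographName", class = "rlnClassNumber")`), and class values are
#' translated to the phi / open / ambiguous vocabulary via `class_map`;
#' unmapped class values become `"ambiguous"` with a warning. Duplicate
#' particle rows are preserved — rows are particles, not unique molecules.
#'
#' @param path CSV or STAR file path.
#' @param mapping Named character vector with entries `micrograph_id` and
#'   `class` naming the source columns.
#' @param class_map Named character vector translating raw class values to
#'   `phi` / `open` / `ambiguous` (names are raw values).
#' @return Tibble with `micrograph_id`, `class_label` (plus any source
#'   columns, untouched).
#' @export
read_particle_table <- function(path,
                                mapping = c(micrograph_id = "micrograph_id", class = "class_label"),
                                class_map = NULL) {
  first <- readLines(path, n = 50L, warn = FALSE)
  is_star <- any(grepl("^\\s*data_", first))
  tab <- if (is_star) read_star_table(path) else read_table_csv(path)
  for (need in c("micrograph_id", "class")) {
    if (!mapping[[need]] %in% names(tab)) {
      abort(sprintf(
        "column '%s' (mapped from '%s') is missing from %s.",
        mapping[[need]], need, path
      ))
    }
  }
  raw <- as.character(tab[[mapping[["class"]]]])
  if (!is.null(class_map)) {
    mapped <- unname(class_map[raw])
    if (anyNA(mapped)) {
      warn(sprintf(
        "%d particle(s) with unmapped class values set to 'ambiguous'.",
        sum(is.na(mapped))
      ))
      mapped[is.na(mapped)] <- "ambiguous"
    }
    raw <- mapped
  }
  bad <- !raw %in% c("phi", "open", "ambiguous")
  if (any(bad)) {
    warn(sprintf("%d particle(s) with unknown labels set to 'ambiguous'.", sum(bad)))
    raw[bad] <- "ambiguous"
  }
  tab$micrograph_id <- as.character(tab[[mapping[["micrograph_id"]]]])
  tab$class_label <- raw
  tibble::as_tibble(tab)
}

# Minimal parser for a single-block STAR loop table. The installed stack has
# no STAR reader, so this handles exactly the dialect we emit: one data_
# block, one loop_, whitespace-separated values, '#' comments.
read_star_table <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  loop_at <- which(lines == "loop_")
  if (length(loop_at) == 0) abort(sprintf("%s: no loop_ block found.", path))
  body <- lines[(loop_at[1] + 1):length(lines)]
  is_tag <- startsWith(body, "_")
  n_tags <- match(FALSE, is_tag) - 1L
  if (is.na(n_tags) || n_tags == 0) abort(sprintf("%s: loop_ block has no column tags.", path))
  tags <- sub("\\s+#.*$", "", body[seq_len(n_tags)])
  tags <- sub("^_", "", tags)
  rows <- body[(n_tags + 1):length(body)]
  rows <- rows[!startsWith(rows, "data_") & rows != "loop_"]
  mat <- do.call(rbind, strsplit(rows, "\\s+"))
  if (ncol(mat) != length(tags)) {
    abort(sprintf("%s: row width does not match %d column tags.", path, length(tags)))
  }
  out <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE))
  names(out) <- tags
  out[] <- lapply(out, utils::type.convert, as.is = TRUE)
  out
}

#' Write particle records as a minimal STAR data table
#'
#' @param records Tibble with `micrograph_id` and `class_label`.
#' @param path Output path.
#' @param block Data block name (default `"particles"`).
#' @return `path`, invisibly.
#' @export
write_star_table <- function(records, path, block = "particles") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("data_%s", block), "", "loop_",
    sprintf("_%s #%d", names(records), seq_along(records))
  ), con)
  writeLines(do.call(paste, c(lapply(records, as.character), sep = "\t")), con)
  invisible(path)
}

#' Write / read an image stack as multi-page TIFF
#'
#' 16-bit multi-page TIFF round-trip for (z, y, x) arrays; intensities are
#' stored as fractions of 65535 by the tiff package, so values must lie in
#' the 16-bit range.
#'
#' @param stack `image_stack` or (z, y, x) array.
#' @param path TIFF path.
#' @return `write_image_stack()` returns `path` invisibly;
#'   `read_image_stack()` a (z, y, x) array.
#' @export
write_image_stack <- function(stack, path) {
  arr <- if (inherits(stack, "image_stack")) stack$data else stack
  pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) arr[z, , ] <- round(pages[[z]] * 65535)
  arr
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("config must be a .yaml, .yml, or .json file.")
  }
}
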