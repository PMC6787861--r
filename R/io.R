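#' Read an LFMC observation table
#'
#' Reads a delimited text file (tab, comma or whitespace separated; the
#' delimiter is auto-detected from the header line) into the validated
#' observation table the modelling functions consume.  Column names in the
#' file are matched through `columns`, a mapping from the canonical names to
#' the file's headers; a calendar-date column, when mapped instead of `day`,
#' is converted to days since the earliest date.  Rows with a missing
#' response are dropped with a message.
#'
#' Leaf-type coding: either a single 4-level code (GW, GE, SM, SS) via the
#' `leaf_type` mapping, or separate `site` + `species` columns (species
#' grass/SM/SS), which are normalised to the 4-level code.
#'
#' @param path Path to the file.
#' @param columns Named list mapping canonical names (`site`, `plot`,
#'   `point`, `leaf_type`, `day`, `date`, `species`, `lfmc`) to the file's
#'   headers.  Defaults to the canonical names themselves.
#' @return A validated tibble with columns `site`, `plot`, `point`,
#'   `leaf_type`, `day`, `lfmc`.
#' @examples
#' path <- system.file("extdata", "lfmc_synthetic.txt",
#'                     package = "fuelmoist")
#' nrow(read_lfmc(path))  # 247
#' @export
read_lfmc <- function(path, columns = list()) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "fuelmoist_empty_input")
  }
  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header)) {
    abort("Input file is empty.", class = "fuelmoist_empty_input")
  }
  delim <- if (grepl("\t", header)) "\t"
  else if (grepl(",", header)) ","
  else NULL
  raw <- if (is.null(delim)) {
    readr::read_table(path, show_col_types = FALSE)
  } else {
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      trim_ws = TRUE)
  }
  if (!nrow(raw)) {
    abort("Input file has a header but no rows.",
          class = "fuelmoist_empty_input")
  }
  map <- utils::modifyList(
    list(site = "site", plot = "plot", point = "point",
         leaf_type = "leaf_type", day = "day", date = "date",
         species = "species", lfmc = "lfmc"),
    columns)
  get_col <- function(nm) {
    cn <- map[[nm]]
    if (!is.null(cn) && cn %in% names(raw)) raw[[cn]] else NULL
  }
  need <- function(nm) {
    v <- get_col(nm)
    if (is.null(v)) {
      abort(paste0("Required column '", nm, "' (mapped to '", map[[nm]],
                   "') not found. Available headers: ",
                   paste(names(raw), collapse = ", ")),
            class = "fuelmoist_schema_error")
    }
    v
  }
  out <- tibble::tibble(site = as.character(need("site")),
                        plot = need("plot"),
                        lfmc = as.numeric(need("lfmc")))
  pt <- get_col("point")
  out$point <- if (is.null(pt)) NA else pt

  lt <- get_col("leaf_type")
  if (is.null(lt)) {
    spp <- get_col("species")
    if (is.null(spp)) {
      abort(paste0("Need either a leaf-type column or a species column. ",
                   "Available headers: ", paste(names(raw), collapse = ", ")),
            class = "fuelmoist_schema_error")
    }
    spp <- toupper(as.character(spp))
    lt <- dplyr::case_when(
      spp %in% c("SM", "MULINUM", "M.SPINOSUM") ~ "SM",
      spp %in% c("SS", "SENECIO", "S.FILAGINOIDES") ~ "SS",
      out$site == "W" ~ "GW",
      TRUE ~ "GE")
  }
  out$leaf_type <- as.character(lt)

  dayv <- get_col("day")
  if (is.null(dayv)) {
    datev <- get_col("date")
    if (is.null(datev)) {
      abort(paste0("Need either a day column or a date column. ",
                   "Available headers: ", paste(names(raw), collapse = ", ")),
            class = "fuelmoist_schema_error")
    }
    datev <- as.Date(datev)
    dayv <- as.numeric(datev - min(datev, na.rm = TRUE))
  }
  out$day <- as.numeric(dayv)

  n0 <- nrow(out)
  out <- out[is.finite(out$lfmc), , drop = FALSE]
  if (n0 - nrow(out) > 0) {
    message(n0 - nrow(out), " row(s) with missing response dropped.")
  }
  if (!nrow(out)) {
    abort("No rows left after dropping missing responses.",
          class = "fuelmoist_empty_input")
  }
  bad <- !out$leaf_type %in% lfmc_leaf_levels()
  if (any(bad)) {
    abort(paste0("Unknown leaf-type code(s): ",
                 paste(unique(out$leaf_type[bad]), collapse = ", ")),
          class = "fuelmoist_labeling_error")
  }
  if (any(out$leaf_type == "GW" & out$site != "W") ||
      any(out$leaf_type != "GW" & out$site == "W")) {
    warn("Leaf-type/site combinations depart from the two-site design.")
  }
  if (anyNA(out$point)) {
    out <- out |>
      dplyr::group_by(.data$site, .data$plot, .data$leaf_type, .data$day) |>
      dplyr::mutate(point = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  out |>
    dplyr::mutate(leaf_type = factor(.data$leaf_type,
                                     levels = lfmc_leaf_levels())) |>
    dplyr::select("site", "plot", "point", "leaf_type", "day", "lfmc")
}

#' Write an LFMC observation table
#'
#' Writes the table as tab-separated text in the same layout [read_lfmc()]
#' consumes, so a write/read round trip is lossless.
#'
#' @param data Observation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lfmc <- function(data, path) {
  d <- dplyr::as_tibble(data) |>
    dplyr::mutate(leaf_type = as.character(.data$leaf_type))
  readr::write_tsv(d, path)
  invisible(path)
}
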