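#' Read occurrence records
#'
#' Records are whitespace- or tab-separated `taxon longitude latitude` rows
#' (the event-model "records" tab dialect); lines starting with `#` are
#' skipped. Coordinates are validated but duplicate rows are retained --
#' collapsing to pixels happens at rasterization time, not here.
#'
#' @param path file to read.
#' @return an `occurrence_table`: a data.frame with columns `taxon`, `lon`,
#'   `lat`.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no records in ", path, call. = FALSE)
  parts <- strsplit(lines, "[\t ]+")
  n <- lengths(parts)
  if (any(n < 3L)) {
    stop("record row ", which(n < 3L)[1L], " does not have 3 fields",
         call. = FALSE)
  }
  taxon <- vapply(parts, `[[`, "", 1L)
  lon <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  lat <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  occurrence_table(taxon, lon, lat)
}

#' Construct an occurrence table
#'
#' @param taxon character vector of taxon labels.
#' @param lon,lat numeric decimal degrees.
#' @return an `occurrence_table` data.frame.
#' @export
occurrence_table <- function(taxon, lon, lat) {
  taxon <- normalize_taxon(taxon)
  if (any(!nzchar(taxon))) {
    stop("empty taxon field in record row ", which(!nzchar(taxon))[1L],
         call. = FALSE)
  }
  if (any(is.na(lon)) || any(is.na(lat))) {
    stop("non-numeric coordinate in record row ",
         which(is.na(lon) | is.na(lat))[1L], call. = FALSE)
  }
  if (any(lon < -180 | lon > 180)) {
    stop("longitude out of [-180, 180] in record row ",
         which(lon < -180 | lon > 180)[1L], call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) {
    stop("latitude out of [-90, 90] in record row ",
         which(lat < -90 | lat > 90)[1L], call. = FALSE)
  }
  structure(data.frame(taxon = taxon, lon = lon, lat = lat,
                       stringsAsFactors = FALSE),
            class = c("occurrence_table", "data.frame"))
}

#' Write occurrence records in the records tab dialect
#'
#' @param records an `occurrence_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  writeLines(sprintf("%s\t%.6g\t%.6g",
                     records$taxon, records$lon, records$lat), path)
  invisible(path)
}

#' Categorical trait table
#'
#' Maps species to one state of a named categorical trait. States carry a
#' declared, ordered label set so state indices are stable even when some
#' state is unobserved.
#'
#' @param trait trait name.
#' @param states ordered character vector of state labels.
#' @param assignments named character vector: species -> state label.
#' @param definitions optional free-text state definitions (same length as
#'   `states`).
#' @return a `trait_table` object.
#' @export
trait_table <- function(trait, states, assignments, definitions = NULL) {
  stopifnot(is.character(states), length(states) >= 1L)
  if (anyDuplicated(states)) stop("duplicate state labels", call. = FALSE)
  species <- normalize_taxon(names(assignments))
  if (is.null(species) || any(!nzchar(species))) {
    stop("assignments must be named by species", call. = FALSE)
  }
  if (anyDuplicated(species)) {
    stop("species assigned more than once: ",
         paste(unique(species[duplicated(species)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(assignments), states)
  if (length(bad)) {
    stop("state label not in declared set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(assignments, states)
  names(idx) <- species
  structure(list(trait = trait, states = states, index = idx,
                 definitions = definitions),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait '%s': %d species, states {%s}\n", x$trait,
              length(x$index), paste(x$states, collapse = ", ")))
  invisible(x)
}

#' Read a trait table
#'
#' The file declares the trait in a header: a line `#trait <name>` and a
#' line `#states <label1> <label2> ...`, followed by `species<TAB>state`
#' rows.
#'
#' @param path file to read.
#' @return a [trait_table()].
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty trait file: ", path, call. = FALSE)
  tr <- grep("^#trait\\s", lines, value = TRUE)
  st <- grep("^#states\\s", lines, value = TRUE)
  if (!length(tr) || !length(st)) {
    stop("trait file must declare '#trait <name>' and '#states ...' headers",
         call. = FALSE)
  }
  trait <- trimws(sub("^#trait\\s+", "", tr[1L]))
  states <- scan(text = sub("^#states\\s+", "", st[1L]), what = "",
                 quiet = TRUE)
  body <- lines[!startsWith(trimws(lines), "#")]
  if (!length(body)) stop("trait file has no species rows", call. = FALSE)
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("trait row ", which(lengths(parts) < 2L)[1L],
         " does not have 'species<TAB>state'", call. = FALSE)
  }
  vals <- vapply(parts, function(p) trimws(p[[2L]]), "")
  names(vals) <- vapply(parts, `[[`, "", 1L)
  trait_table(trait, states, vals)
}

#' Write a trait table
#'
#' @param x a [trait_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(x, path) {
  writeLines(c(paste("#trait", x$trait),
               paste("#states", paste(x$states, collapse = " ")),
               paste0(names(x$index), "\t", x$states[x$index])), path)
  invisible(path)
}
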