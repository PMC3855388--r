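## File-based identifier translation between systems, used when the seed
## network's identifier system differs from those embedded in the RegINs.
## The table is a TSV whose header names the systems; each row holds
## synonymous identifiers (empty cell = no identifier in that system).
## Many-to-many mappings are preserved, never silently resolved.

#' Construct a mapping table in memory
#'
#' @param systems Character vector of system names (no duplicates).
#' @param rows Character matrix (or data.frame) with one column per system;
#'   "" marks a missing identifier.
#' @return A [MappingTable-class].
#' @export
mappingTable <- function(systems, rows) {
  rows <- as.matrix(rows)
  if (!length(rows)) {
    rows <- matrix(character(), nrow = 0L, ncol = length(systems))
  }
  storage.mode(rows) <- "character"
  rows[is.na(rows)] <- ""
  dimnames(rows) <- list(NULL, systems)
  new("MappingTable", systems = as.character(systems), rows = rows)
}

#' Load an identifier mapping table from a TSV file
#'
#' The first row is a header of identifier-system names; each following row
#' lists synonymous identifiers, one column per system, empty cell meaning
#' no identifier in that system. Duplicate header names and ragged rows are
#' errors.
#'
#' @param path Path to the TSV file (Windows/Unix line endings and a UTF-8
#'   BOM are tolerated).
#' @return A [MappingTable-class].
#' @seealso [translateIds()], [expandSeedIds()]
#' @export
loadMappingTable <- function(path) {
  lines <- .readLinesClean(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop(sprintf("empty mapping table '%s'", path))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  systems <- cells[[1L]]
  if (anyDuplicated(systems)) {
    stop("duplicate system name(s) in mapping table header: ",
         paste(unique(systems[duplicated(systems)]), collapse = ", "))
  }
  ns <- length(systems)
  rows <- matrix("", nrow = length(cells) - 1L, ncol = ns)
  for (i in seq_along(cells)[-1L]) {
    row <- cells[[i]]
    # trailing empty cells are dropped by strsplit; pad them back
    if (length(row) < ns) row <- c(row, rep("", ns - length(row)))
    if (length(row) != ns) {
      stop(sprintf("mapping table row %d has %d cells, expected %d",
                   i, length(row), ns))
    }
    rows[i - 1L, ] <- row
  }
  mappingTable(systems, rows)
}

#' Translate identifiers between systems
#'
#' Returns the union of \code{to} cells over all rows whose \code{from}
#' cell equals the queried value (exact, case-sensitive). Many-to-many
#' mappings return every hit; an unmapped value returns an empty set.
#' Identity translation returns the value itself whenever it occurs in the
#' \code{from} column.
#'
#' @param values Character vector of identifiers to translate.
#' @param from,to System names present in the table.
#' @param table A [MappingTable-class].
#' @return Character vector (sorted, unique) of translated identifiers.
#' @export
translateIds <- function(values, from, to, table) {
  stopifnot(is(table, "MappingTable"))
  for (sys in c(from, to)) {
    if (!sys %in% table@systems) {
      stop(sprintf("unknown system '%s'; available systems: %s", sys,
                   paste(table@systems, collapse = ", ")))
    }
  }
  fromCol <- table@rows[, match(from, table@systems)]
  toCol <- table@rows[, match(to, table@systems)]
  hits <- toCol[fromCol %in% values & nzchar(fromCol)]
  sort(unique(hits[nzchar(hits)]), method = "radix")
}

#' Expand seed identifiers with translations
#'
#' For every seed node, the id-attribute value(s) become the union of the
#' original value(s) and their translations into each of
#' \code{targetSystems}; the originals are always retained, so matching can
#' only gain, never lose. Untranslatable values pass through unchanged and
#' are counted in the returned attribute \code{"untranslated"}.
#'
#' @param seed A [SeedNetwork-class] whose id-attribute values come from
#'   system \code{seedSystem}.
#' @param table A [MappingTable-class]; NULL returns the seed unchanged.
#' @param seedSystem System of the seed's id-attribute values.
#' @param targetSystems Systems to translate into.
#' @return The expanded [SeedNetwork-class]; the number of values that had
#'   no translation into any target system is attached as attribute
#'   \code{"untranslated"}.
#' @export
expandSeedIds <- function(seed, table, seedSystem, targetSystems) {
  stopifnot(is(seed, "SeedNetwork"))
  if (is.null(table)) return(seed)
  stopifnot(is(table, "MappingTable"))
  untranslated <- 0L
  attrName <- seed@idAttribute
  attrs <- seed@nodes$attrs
  for (i in seq_along(attrs)) {
    vals <- attrs[[i]][[attrName]]
    if (is.null(vals)) next
    vals <- as.character(vals)
    extra <- character()
    for (sys in targetSystems) {
      extra <- c(extra, translateIds(vals, seedSystem, sys, table))
    }
    if (!length(extra)) untranslated <- untranslated + 1L
    attrs[[i]][[attrName]] <- unique(c(vals, extra))
  }
  seed@nodes$attrs <- I(attrs)
  attr(seed, "untranslated") <- untranslated
  seed
}
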