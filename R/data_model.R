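## Table schemas for the published CSV layout of the spacing-trial dataset.
## Units are kept exactly as published: diameters mm, heights dm, crown radii
## m, ring widths 1/100 mm. An empty CSV field means "absent"; "0" is always
## a value (several code lists include 0).

SPECIES_CODES <- c("PCAB", "LADC", "PNSY", "FASY", "QCPE", "BTPE")

#' Table schemas of the spacing-trial dataset
#'
#' Returns the column names, column types, coded-value domains and key
#' columns of the eleven CSV tables handled by the package. Schema names:
#' `corner`, `area`, `pos`, `date`, `dbhObs`, `crown`, `secDiam`, `saTree`,
#' `saIr`, `saDisc`, `dhcComplSmooth`.
#'
#' @return named list; each element has `columns` (named character vector of
#'   types), `domains` (allowed values for coded columns) and `key`.
#' @export
dc_schemas <- function() {
  sch <- list(
    corner = list(
      columns = c(plot = "integer", corner = "integer", cor = "logical",
                  x = "numeric", y = "numeric", lon = "numeric", lat = "numeric"),
      domains = list(plot = 1:4),
      key = c("plot", "corner")),
    area = list(
      columns = c(plot = "integer", area = "numeric"),
      domains = list(plot = 1:4),
      key = "plot"),
    pos = list(
      columns = c(plot = "integer", tree = "integer", x = "numeric",
                  y = "numeric", z = "numeric", species = "character",
                  posObs = "logical", germinationYear = "integer",
                  core = "logical", removeDate = "date", removeal = "integer",
                  lon = "numeric", lat = "numeric"),
      domains = list(plot = 1:4, species = SPECIES_CODES, removeal = 1:9),
      key = c("plot", "tree")),
    date = list(
      columns = c(plot = "integer", year = "integer", obs = "integer",
                  date = "date"),
      domains = list(plot = 1:4),
      key = c("plot", "year", "obs")),
    dbhObs = list(
      columns = c(plot = "integer", tree = "integer", year = "integer",
                  obs = "integer", dbh = "numeric", dbh2 = "numeric",
                  hmk = "integer", kh = "integer", ho = "numeric",
                  ka = "numeric", kb = "numeric", wka = "numeric",
                  kraft = "integer", crown = "integer", stem = "integer",
                  defoliation = "integer"),
      domains = list(plot = 1:4, hmk = 1:7, kh = 0:1, kraft = 1:5,
                     crown = 0:6, stem = 0:9, defoliation = 1:3),
      key = c("plot", "tree", "year", "obs")),
    crown = list(
      columns = c(plot = "integer", tree = "integer", year = "integer",
                  obs = "integer",
                  d17 = "numeric", d62 = "numeric", d107 = "numeric",
                  d152 = "numeric", d197 = "numeric", d242 = "numeric",
                  d287 = "numeric", d332 = "numeric"),
      domains = list(plot = 1:4),
      key = c("plot", "tree", "year", "obs")),
    secDiam = list(
      columns = c(plot = "integer", tree = "integer", year = "integer",
                  species = "character", length = "numeric", dbh = "numeric",
                  crownLength = "numeric", crownWidth = "numeric",
                  stats::setNames(rep("numeric", 27), paste0("m", 1:27))),
      domains = list(plot = 1:4, species = SPECIES_CODES),
      key = c("plot", "tree", "year")),
    saTree = list(
      columns = c(plot = "integer", tree = "integer", species = "character",
                  dbh = "numeric", height = "numeric", hKrown = "numeric"),
      domains = list(plot = 1:4, species = SPECIES_CODES),
      key = c("plot", "tree")),
    saIr = list(
      columns = c(plot = "integer", tree = "integer", disc = "integer",
                  dir = "character", year = "integer", ir = "numeric"),
      domains = list(plot = 1:4),
      key = c("plot", "tree", "disc", "dir", "year")),
    saDisc = list(
      columns = c(plot = "integer", tree = "integer", disc = "integer",
                  h = "numeric"),
      domains = list(plot = 1:4),
      key = c("plot", "tree", "disc")),
    dhcComplSmooth = list(
      columns = c(plot = "integer", tree = "integer", year = "integer",
                  obs = "integer", d = "numeric", h = "numeric",
                  hCr = "numeric"),
      domains = list(plot = 1:4),
      key = c("plot", "tree", "year", "obs"))
  )
  sch
}

get_schema <- function(schema) {
  sch <- dc_schemas()
  if (!schema %in% names(sch))
    stop("unknown schema: ", schema, call. = FALSE)
  sch[[schema]]
}

convert_column <- function(x, type) {
  x[x == ""] <- NA
  switch(type,
    integer = {
      v <- suppressWarnings(as.integer(x))
      if (any(!is.na(x) & is.na(v))) stop("non-integer value")
      v
    },
    numeric = {
      v <- suppressWarnings(as.numeric(x))
      if (any(!is.na(x) & is.na(v))) stop("non-numeric value")
      v
    },
    logical = {
      v <- rep(NA, length(x))
      v[x %in% c("TRUE", "true", "T")] <- TRUE
      v[x %in% c("FALSE", "false", "F")] <- FALSE
      if (any(!is.na(x) & is.na(v))) stop("non-logical value")
      as.logical(v)
    },
    date = {
      v <- as.Date(rep(NA_character_, length(x)))
      ok <- !is.na(x)
      if (any(ok)) {
        parsed <- as.Date(x[ok], format = "%Y-%m-%d")
        if (any(is.na(parsed))) stop("unparseable date")
        v[ok] <- parsed
      }
      v
    },
    character = as.character(x),
    stop("unknown column type ", type))
}

check_domains <- function(df, sch, table_name = "table") {
  issues <- character(0)
  for (col in names(sch$domains)) {
    if (!col %in% names(df)) next
    bad <- which(!is.na(df[[col]]) & !(df[[col]] %in% sch$domains[[col]]))
    if (length(bad))
      issues <- c(issues, sprintf(
        "%s: column '%s' out of domain in row(s) %s (value(s) %s)",
        table_name, col, paste(utils::head(bad, 5L), collapse = ","),
        paste(unique(df[[col]][utils::head(bad, 5L)]), collapse = ",")))
  }
  issues
}

#' Read one published CSV table
#'
#' Reads and type-checks a table against its schema: the header must match
#' the published column names exactly, coded fields must lie in their
#' published domains, dates must parse as `YYYY-MM-DD`. Empty fields become
#' `NA`; `"0"` is a value, never absent.
#'
#' @param path path to the CSV file.
#' @param schema schema name, see [dc_schemas()].
#' @return a typed `data.frame`.
#' @export
read_table <- function(path, schema) {
  sch <- get_schema(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  if (!identical(names(raw), names(sch$columns)))
    stop(sprintf("schema error: header of %s does not match schema '%s'\n  expected: %s\n  found:    %s",
                 path, schema, paste(names(sch$columns), collapse = ","),
                 paste(names(raw), collapse = ",")))
  out <- raw
  for (col in names(sch$columns)) {
    out[[col]] <- tryCatch(convert_column(raw[[col]], sch$columns[[col]]),
      error = function(e) stop(sprintf("column '%s' of %s: %s",
                                       col, path, conditionMessage(e)),
                               call. = FALSE))
  }
  issues <- check_domains(out, sch, basename(path))
  if (length(issues))
    stop("validation error:\n  ", paste(issues, collapse = "\n  "), call. = FALSE)
  out
}

format_table <- function(df, sch) {
  out <- df
  for (col in names(sch$columns)) {
    type <- sch$columns[[col]]
    x <- df[[col]]
    s <- if (type == "date") format(x, "%Y-%m-%d")
         else if (type == "numeric") {
           # fixed notation, trailing zeros trimmed: stable across runs
           vapply(x, function(z) {
             if (is.na(z)) return(NA_character_)
             s <- format(z, scientific = FALSE, trim = TRUE, digits = 15)
             if (grepl(".", s, fixed = TRUE)) s <- sub("\\.?0+$", "", s)
             s
           }, character(1))
         }
         else as.character(x)
    s[is.na(s)] <- ""
    out[[col]] <- s
  }
  out
}

#' Write a table in the published CSV layout
#'
#' Checks the schema invariants, then writes a CSV with the published column
#' names, empty fields for absent values, and stable numeric formatting, so
#' that read -> write -> read is the identity on values and a second write is
#' bit-identical.
#'
#' @param records a `data.frame` conforming to the schema.
#' @param schema schema name.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, schema, path) {
  sch <- get_schema(schema)
  if (!identical(names(records), names(sch$columns)))
    stop("records do not match schema '", schema, "' columns")
  issues <- check_domains(records, sch, schema)
  if (schema == "dhcComplSmooth") {
    bad <- which(!is.na(records$hCr) & !is.na(records$h) & records$hCr > records$h + 1e-9)
    if (length(bad))
      issues <- c(issues, sprintf("dhcComplSmooth: hCr > h in row(s) %s",
                                  paste(utils::head(bad, 5L), collapse = ",")))
  }
  if (schema == "pos") {
    bad <- which(is.na(records$removeDate) != is.na(records$removeal))
    if (length(bad))
      issues <- c(issues, sprintf("pos: removeal must be present iff removeDate is, row(s) %s",
                                  paste(utils::head(bad, 5L), collapse = ",")))
  }
  if (length(issues))
    stop("refusing to write invalid records:\n  ",
         paste(issues, collapse = "\n  "), call. = FALSE)
  fmt <- format_table(records, sch)
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

add_issue <- function(report, table, type, message) {
  rbind(report, data.frame(table = table, type = type, message = message,
                           stringsAsFactors = FALSE))
}

#' Cross-table consistency report
#'
#' Validates a loaded dataset (a named list of tables, as produced by
#' [simulate_stand()] or by reading the published files) against the
#' cross-table invariants: unique keys, referential integrity from the
#' observation tables into `pos` and `date`, code domains, and observations
#' recorded after a tree's removal date. Issues are reported, never raised.
#'
#' @param tables named list of data.frames (names are schema names).
#' @return a `data.frame` with columns `table`, `type`, `message`; zero rows
#'   when the dataset is consistent.
#' @export
validate_dataset <- function(tables) {
  report <- data.frame(table = character(0), type = character(0),
                       message = character(0), stringsAsFactors = FALSE)
  sch <- dc_schemas()
  for (nm in names(tables)) {
    if (!nm %in% names(sch)) next
    df <- tables[[nm]]
    for (msg in check_domains(df, sch[[nm]], nm))
      report <- add_issue(report, nm, "domain", msg)
    key <- sch[[nm]]$key
    if (all(key %in% names(df)) && nrow(df)) {
      kk <- do.call(paste, c(df[key], sep = "\r"))
      dup <- unique(kk[duplicated(kk)])
      if (length(dup))
        report <- add_issue(report, nm, "duplicate-key",
          sprintf("%s: %d duplicated key value(s) on (%s)", nm, length(dup),
                  paste(key, collapse = ",")))
    }
  }
  pos <- tables$pos; dbh <- tables$dbhObs; cal <- tables$date
  if (!is.null(pos) && !is.null(dbh) && nrow(dbh)) {
    posKey <- paste(pos$plot, pos$tree)
    miss <- !(paste(dbh$plot, dbh$tree) %in% posKey)
    if (any(miss))
      report <- add_issue(report, "dbhObs", "referential",
        sprintf("dbhObs: %d row(s) reference (plot,tree) absent from pos, first row %d",
                sum(miss), which(miss)[1]))
  }
  if (!is.null(cal) && !is.null(dbh) && nrow(dbh)) {
    calKey <- paste(cal$plot, cal$year, cal$obs)
    miss <- !(paste(dbh$plot, dbh$year, dbh$obs) %in% calKey)
    if (any(miss))
      report <- add_issue(report, "dbhObs", "referential",
        sprintf("dbhObs: %d row(s) have no matching campaign in date.csv, first row %d",
                sum(miss), which(miss)[1]))
    if (nrow(cal)) {
      # dates strictly increasing within a plot
      for (p in unique(cal$plot)) {
        d <- cal$date[cal$plot == p][order(cal$year[cal$plot == p], cal$obs[cal$plot == p])]
        if (anyNA(d) || any(diff(as.numeric(d)) <= 0))
          report <- add_issue(report, "date", "temporal",
            sprintf("date: campaign dates not strictly increasing on plot %s", p))
      }
    }
  }
  if (!is.null(pos) && !is.null(dbh) && !is.null(cal) && nrow(dbh)) {
    m <- merge(dbh[c("plot", "tree", "year", "obs")], cal, by = c("plot", "year", "obs"))
    m <- merge(m, pos[c("plot", "tree", "removeDate")], by = c("plot", "tree"))
    late <- !is.na(m$removeDate) & !is.na(m$date) & m$date > m$removeDate
    if (any(late))
      report <- add_issue(report, "dbhObs", "temporal",
        sprintf("dbhObs: %d observation(s) dated after the tree's removeDate (e.g. plot %d tree %d year %d)",
                sum(late), m$plot[late][1], m$tree[late][1], m$year[late][1]))
  }
  report
}
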