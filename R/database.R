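#' Write a non-redundant ESS set to an SQLite database
#'
#' The relational layout mirrors how the sequences are produced: a
#' non-redundant sequence table `nrseqs(ess_id, seq3, seq4)` (with `seq3`
#' unique — the non-redundancy constraint), `organisms(org, domain)`,
#' `maps(map_id)`, and `links(ess_id, org, map_id, step_index, gene_id)`
#' relating every EC step of every original occurrence of a representative
#' back to its gene(s), organism and metabolic map.
#'
#' @param nress either the list returned by [make_nonredundant()] or a
#'   plain list of `ess` objects (each then stands only for itself).
#' @param path destination SQLite file.
#' @param domains optional named character vector mapping organism codes to
#'   a domain of life (`Bacteria`, `Archaea`, `Eukarya`).
#' @param overwrite replace an existing file (default `FALSE`: appending to
#'   an existing database is an error).
#' @return the path, invisibly.
#' @export
write_ess_db <- function(nress, path, domains = NULL, overwrite = FALSE) {
  if (is.list(nress) && !is.null(nress$nress)) {
    ess_list <- nress$nress
    redundancy <- nress$redundancy
  } else {
    ess_list <- nress
    redundancy <- NULL
  }
  if (file.exists(path)) {
    if (!overwrite) stop(sprintf("'%s' already exists", path), call. = FALSE)
    unlink(path)
  }
  con <- tryCatch(DBI::dbConnect(RSQLite::SQLite(), path),
                  error = function(e) {
                    stop(sprintf("cannot write database '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "CREATE TABLE nrseqs (
      ess_id INTEGER PRIMARY KEY,
      seq3 TEXT NOT NULL UNIQUE,
      seq4 TEXT NOT NULL)")
  DBI::dbExecute(con, "CREATE TABLE organisms (
      org TEXT PRIMARY KEY, domain TEXT)")
  DBI::dbExecute(con, "CREATE TABLE maps (map_id TEXT PRIMARY KEY)")
  DBI::dbExecute(con, "CREATE TABLE links (
      ess_id INTEGER NOT NULL REFERENCES nrseqs(ess_id),
      org TEXT, map_id TEXT, step_index INTEGER, gene_id TEXT)")

  orgs <- character(0L)
  maps <- character(0L)
  for (i in seq_along(ess_list)) {
    e <- ess_list[[i]]
    key <- format_ess(e$labels3)
    DBI::dbExecute(con, "INSERT INTO nrseqs (ess_id, seq3, seq4) VALUES (?, ?, ?)",
                   params = list(i, key, format_ess(e$labels4)))
    occurrences <- if (!is.null(redundancy) && !is.null(redundancy[[key]])) {
      redundancy[[key]]
    } else {
      list(list(organism = e$organism, map_id = e$map_id, genes = e$genes))
    }
    for (occ in occurrences) {
      orgs <- union(orgs, occ$organism)
      maps <- union(maps, occ$map_id)
      for (s in seq_along(occ$genes)) {
        for (g in occ$genes[[s]]) {
          DBI::dbExecute(con,
            "INSERT INTO links (ess_id, org, map_id, step_index, gene_id)
             VALUES (?, ?, ?, ?, ?)",
            params = list(i, occ$organism, occ$map_id, s, g))
        }
      }
    }
  }
  for (o in orgs) {
    dom <- if (!is.null(domains) && o %in% names(domains)) domains[[o]] else NA
    DBI::dbExecute(con, "INSERT INTO organisms (org, domain) VALUES (?, ?)",
                   params = list(o, dom))
  }
  for (m in maps) {
    DBI::dbExecute(con, "INSERT INTO maps (map_id) VALUES (?)",
                   params = list(m))
  }
  invisible(path)
}

is_sqlite_file <- function(path) {
  if (!file.exists(path) || dir.exists(path)) return(FALSE)
  if (file.size(path) < 16L) return(FALSE)
  hdr <- readBin(path, "raw", 15L)
  identical(rawToChar(hdr), "SQLite format 3")
}

#' Read ESS from an SQLite database or a one-per-line text file
#'
#' Accepts either an SQLite file containing an `nrseqs` table (as written
#' by [write_ess_db()]) or a plain-text file with one colon-separated ESS
#' per line.  Text files assign 1-based line numbers as ids.
#'
#' @param source file path.
#' @return data.frame with columns `ess_id` (integer) and `seq3`
#'   (character), ordered by id.
#' @export
read_sequences <- function(source) {
  if (!is.character(source) || length(source) != 1L || !file.exists(source)) {
    stop(sprintf("cannot read ESS source '%s'", source), call. = FALSE)
  }
  if (is_sqlite_file(source)) {
    con <- DBI::dbConnect(RSQLite::SQLite(), source)
    on.exit(DBI::dbDisconnect(con))
    if (!DBI::dbExistsTable(con, "nrseqs")) {
      stop(sprintf("'%s' is an SQLite file without an nrseqs table", source),
           call. = FALSE)
    }
    df <- DBI::dbGetQuery(con, "SELECT ess_id, seq3 FROM nrseqs ORDER BY ess_id")
    df$ess_id <- as.integer(df$ess_id)
    return(df)
  }
  lines <- readLines(source, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  seqs <- character(length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[[k]]
    parsed <- tryCatch(parse_ess(trimws(lines[[ln]])), error = function(e) e)
    if (inherits(parsed, "error")) {
      stop(sprintf("format error at line %d of '%s': %s", ln, source,
                   conditionMessage(parsed)), call. = FALSE)
    }
    seqs[[k]] <- format_ess(parsed)
  }
  data.frame(ess_id = keep, seq3 = seqs, stringsAsFactors = FALSE)
}
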