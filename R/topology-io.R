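## GROMACS itp dialect reader/writer for coarse-grained topologies.
## Sections handled: [moleculetype], [atoms], [bonds], [constraints],
## [angles]. Whitespace-tolerant; comments are preserved on write. Fragment
## roles are carried as "; role=<role>" annotations on [atoms] lines.

.emptyBeads <- function() data.frame(
  name = character(), type = character(), charge = numeric(),
  role = character(), comment = character(), stringsAsFactors = FALSE)

.emptyBonds <- function() data.frame(
  i = integer(), j = integer(), funct = integer(), length = numeric(),
  k = numeric(), comment = character(), stringsAsFactors = FALSE)

.emptyConstraints <- function() data.frame(
  i = integer(), j = integer(), funct = integer(), length = numeric(),
  comment = character(), stringsAsFactors = FALSE)

.emptyAngles <- function() data.frame(
  i = integer(), j = integer(), k = integer(), funct = integer(),
  angle = numeric(), force = numeric(), comment = character(),
  stringsAsFactors = FALSE)

#' Construct a CGTopology
#'
#' @param molecule molecule name
#' @param beads data.frame with name, type, charge, role (and optionally
#'   comment)
#' @param bonds data.frame with i, j, length, k (optionally funct, comment)
#' @param constraints data.frame with i, j, length
#' @param angles data.frame with i, j, k, angle, force
#' @param header comment lines written at the top of the itp file
#' @return a \linkS4class{CGTopology}
#' @export
newCGTopology <- function(molecule, beads, bonds = NULL, constraints = NULL,
                          angles = NULL, header = character()) {
  fill <- function(df, tmpl) {
    if (is.null(df) || nrow(df) == 0L) return(tmpl)
    defaults <- list(funct = if ("angle" %in% names(tmpl)) 2L else 1L,
                     comment = "", role = NA_character_)
    for (col in names(tmpl)) if (!col %in% names(df))
      df[[col]] <- if (col %in% names(defaults)) defaults[[col]] else NA
    df$comment[is.na(df$comment)] <- ""
    rownames(df) <- NULL
    df[, names(tmpl), drop = FALSE]
  }
  beads <- fill(beads, .emptyBeads())
  new("CGTopology", molecule = molecule, beads = beads,
      bonds = fill(bonds, .emptyBonds()),
      constraints = fill(constraints, .emptyConstraints()),
      angles = fill(angles, .emptyAngles()),
      header = header)
}

## Split an itp data line into (fields, comment).
.itpLine <- function(line) {
  parts <- strsplit(line, ";", fixed = TRUE)[[1]]
  body <- trimws(parts[1])
  comment <- if (length(parts) > 1L) trimws(paste(parts[-1],
                                                  collapse = ";")) else ""
  list(fields = if (nzchar(body)) strsplit(body, "\\s+")[[1]] else character(),
       comment = comment)
}

#' Read a coarse-grained topology from an itp file
#'
#' @param path itp file with a single [moleculetype]
#' @return a \linkS4class{CGTopology}
#' @export
readITP <- function(path) {
  lines <- readLines(path)
  section <- ""
  molecule <- NA_character_
  header <- character()
  beads <- list(); bonds <- list(); constraints <- list(); angles <- list()
  seenSection <- FALSE
  for (line in lines) {
    t <- trimws(line)
    if (!nzchar(t)) next
    if (grepl("^\\[", t)) {
      section <- tolower(gsub("[][ ]", "", t))
      seenSection <- TRUE
      next
    }
    if (startsWith(t, ";")) {
      if (!seenSection) header <- c(header, sub("^;\\s?", "", t))
      next
    }
    p <- .itpLine(t)
    f <- p$fields
    if (section == "moleculetype") {
      molecule <- f[1]
    } else if (section == "atoms") {
      role <- if (grepl("role=", p$comment))
        sub(".*role=([a-z]+).*", "\\1", p$comment) else NA_character_
      beads[[length(beads) + 1L]] <- data.frame(
        name = f[5], type = f[2], charge = as.numeric(f[7]), role = role,
        comment = p$comment, stringsAsFactors = FALSE)
    } else if (section == "bonds") {
      bonds[[length(bonds) + 1L]] <- data.frame(
        i = as.integer(f[1]), j = as.integer(f[2]), funct = as.integer(f[3]),
        length = as.numeric(f[4]), k = as.numeric(f[5]),
        comment = p$comment, stringsAsFactors = FALSE)
    } else if (section == "constraints") {
      constraints[[length(constraints) + 1L]] <- data.frame(
        i = as.integer(f[1]), j = as.integer(f[2]), funct = as.integer(f[3]),
        length = as.numeric(f[4]), comment = p$comment,
        stringsAsFactors = FALSE)
    } else if (section == "angles") {
      angles[[length(angles) + 1L]] <- data.frame(
        i = as.integer(f[1]), j = as.integer(f[2]), k = as.integer(f[3]),
        funct = as.integer(f[4]), angle = as.numeric(f[5]),
        force = as.numeric(f[6]), comment = p$comment,
        stringsAsFactors = FALSE)
    }
  }
  if (is.na(molecule)) stop("no [moleculetype] section in ", path,
                            call. = FALSE)
  newCGTopology(molecule,
                do.call(rbind, beads), do.call(rbind, bonds),
                do.call(rbind, constraints), do.call(rbind, angles),
                header = header)
}

#' Write a coarse-grained topology as an itp file
#'
#' Fragment-role annotations and term comments are written back, so a
#' write/read round trip preserves every term.
#'
#' @param top a \linkS4class{CGTopology}
#' @param path output file
#' @export
writeITP <- function(top, path) {
  stopifnot(is(top, "CGTopology"))
  out <- character()
  if (length(top@header)) out <- c(out, paste(";", top@header))
  out <- c(out, "[ moleculetype ]", "; molname  nrexcl",
           sprintf("%s  1", top@molecule), "", "[ atoms ]",
           ";  id type resnr residue atom cgnr charge")
  b <- top@beads
  for (r in seq_len(nrow(b))) {
    cm <- b$comment[r]
    if (!is.na(b$role[r]) && !grepl("role=", cm))
      cm <- trimws(paste(cm, sprintf("role=%s", b$role[r])))
    out <- c(out, sprintf("%4d %-5s 1 %-5s %-5s %4d %8.4f%s",
                          r, b$type[r], top@molecule, b$name[r], r,
                          b$charge[r],
                          if (nzchar(cm)) paste0(" ; ", cm) else ""))
  }
  term <- function(df, title, fmt, cols) {
    if (!nrow(df)) return(character())
    lines <- vapply(seq_len(nrow(df)), function(r) {
      vals <- lapply(cols, function(cl) df[[cl]][r])
      base <- do.call(sprintf, c(list(fmt), vals))
      cm <- df$comment[r]
      if (!is.na(cm) && nzchar(cm)) paste0(base, " ; ", cm) else base
    }, character(1))
    c("", paste0("[ ", title, " ]"), lines)
  }
  out <- c(out,
           term(top@bonds, "bonds", "%4d %4d %2d %8.4f %10.2f",
                c("i", "j", "funct", "length", "k")),
           term(top@constraints, "constraints", "%4d %4d %2d %8.4f",
                c("i", "j", "funct", "length")),
           term(top@angles, "angles", "%4d %4d %4d %2d %8.2f %8.2f",
                c("i", "j", "k", "funct", "angle", "force")))
  writeLines(out, path)
  invisible(path)
}

#' Load a shipped coarse-grained template topology
#'
#' Templates with fragment-role annotations ship for the Martini 2.2 and
#' Martini 3 dialects: POPG and POPE lipids, cysteine, and a palmitoyl tail
#' fragment.
#'
#' @param name one of "popg", "pope", "cys", "palmitoyl"
#' @param forcefield "martini22" or "martini3"
#' @return a \linkS4class{CGTopology}
#' @export
templateTopology <- function(name = c("popg", "pope", "cys", "palmitoyl"),
                             forcefield = c("martini22", "martini3")) {
  name <- match.arg(name)
  forcefield <- match.arg(forcefield)
  path <- system.file("extdata", sprintf("%s_%s.itp", forcefield, name),
                      package = "LipoCG", mustWork = TRUE)
  readITP(path)
}
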