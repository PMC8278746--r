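#' Read a brat standoff annotation pair
#'
#' Parses the `.txt`/`.ann` representation used by the brat annotation
#' tool: `T` lines are entity spans (`T1<TAB>LABEL start end<TAB>surface`),
#' `R` lines are binary relations (`R1<TAB>LABEL Arg1:Ti Arg2:Tj`).  Other
#' line types (events, attributes, normalizations, notes) are skipped with
#' a warning.  Discontinuous spans (semicolon-separated fragments) are not
#' part of this annotation scheme and are rejected.
#'
#' @param text_content the raw document text.
#' @param ann_content the standoff annotation as a single string (or
#'   character vector of lines).
#' @param doc_id identifier for the resulting document.
#' @param tokens optional pre-built token layer; default runs
#'   [tokenize_text()].
#' @return An [fh_document()].
#' @export
read_brat <- function(text_content, ann_content, doc_id = "doc", tokens = NULL) {
  lines <- if (length(ann_content) == 1)
    strsplit(ann_content, "\n", fixed = TRUE)[[1]] else ann_content
  lines <- lines[nzchar(trimws(lines))]
  ents <- list(); rels <- list(); skipped <- character()
  for (line in lines) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    id <- fields[1]
    kind <- substr(id, 1, 1)
    if (kind == "T") {
      if (length(fields) < 2) stop("malformed entity line: ", line)
      if (grepl(";", fields[2], fixed = TRUE))
        stop("discontinuous span not supported (entities are continuous text spans): ", line)
      parts <- strsplit(trimws(fields[2]), " +")[[1]]
      if (length(parts) != 3) stop("malformed entity line: ", line)
      start <- suppressWarnings(as.integer(parts[2]))
      end <- suppressWarnings(as.integer(parts[3]))
      if (is.na(start) || is.na(end) || start >= end)
        stop("malformed offsets in entity line: ", line)
      ents[[length(ents) + 1L]] <- data.frame(
        id = id, label = parts[1], start = start, end = end,
        text = substr(text_content, start + 1L, end))
    } else if (kind == "R") {
      parts <- strsplit(trimws(fields[2]), " +")[[1]]
      if (length(parts) != 3 || !all(grepl("^Arg[12]:", parts[2:3])))
        stop("malformed relation line: ", line)
      rels[[length(rels) + 1L]] <- data.frame(
        id = id, label = parts[1],
        arg1 = sub("^Arg1:", "", parts[2]), arg2 = sub("^Arg2:", "", parts[3]))
    } else {
      skipped <- c(skipped, kind)
    }
  }
  if (length(skipped) > 0)
    warning("skipped ", length(skipped), " non-entity/relation annotation line(s) of type ",
            paste(unique(skipped), collapse = ","), " in ", doc_id)
  entities <- if (length(ents)) do.call(rbind, ents) else empty_entities()
  relations <- if (length(rels)) do.call(rbind, rels) else empty_relations()
  dangling <- setdiff(c(relations$arg1, relations$arg2), entities$id)
  if (length(dangling) > 0)
    stop("dangling relation argument(s) in ", doc_id, ": ",
         paste(dangling, collapse = ", "))
  fh_document(doc_id, text_content, tokens = tokens,
              entities = entities, relations = relations)
}

#' Write a document as brat standoff
#'
#' @param doc an [fh_document()].
#' @return A list with elements `text` and `ann` (single strings).
#'   Re-reading the pair with [read_brat()] yields an equivalent document.
#' @export
write_brat <- function(doc) {
  stopifnot(inherits(doc, "fh_document"))
  ents <- doc$entities
  if (any(ents$end > nchar(doc$text)))
    stop("entity out of text bounds in ", doc$doc_id)
  t_lines <- if (nrow(ents) > 0)
    sprintf("%s\t%s %d %d\t%s", ents$id, ents$label, ents$start, ents$end,
            substr(rep(doc$text, nrow(ents)), ents$start + 1L, ents$end))
    else character()
  rels <- doc$relations
  r_lines <- if (nrow(rels) > 0)
    sprintf("%s\t%s Arg1:%s Arg2:%s", rels$id, rels$label, rels$arg1, rels$arg2)
    else character()
  list(text = doc$text,
       ann = paste0(paste(c(t_lines, r_lines), collapse = "\n"),
                    if (length(t_lines) + length(r_lines) > 0) "\n" else ""))
}

#' Read / write a brat project directory
#'
#' A brat project is a directory of `<name>.txt` / `<name>.ann` pairs;
#' when a `<name>.conllu` file is present alongside, its token, POS and
#' dependency layers are attached via [attach_conllu()].
#'
#' @param dir directory path (searched recursively).
#' @param attach_conllu attach sibling `.conllu` files when present.
#' @return A list of [fh_document()]s, one per `.txt`/`.ann` pair, named
#'   by file stem.
#' @export
read_brat_project <- function(dir, attach_conllu = TRUE) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", recursive = TRUE, full.names = TRUE))
  docs <- list()
  for (txt in txts) {
    ann <- sub("\\.txt$", ".ann", txt)
    if (!file.exists(ann)) next
    stem <- sub("\\.txt$", "", basename(txt))
    text <- read_file_utf8(txt)
    doc <- read_brat(text, read_file_utf8(ann), doc_id = stem)
    cfile <- sub("\\.txt$", ".conllu", txt)
    if (attach_conllu && file.exists(cfile))
      doc <- attach_conllu(doc, read_file_utf8(cfile))
    docs[[stem]] <- doc
  }
  if (length(docs) == 0) stop("no .txt/.ann pairs found under ", dir)
  docs
}

#' @rdname read_brat_project
#' @param corpus list of [fh_document()]s.
#' @param write_conllu also write a `.conllu` file per document.
#' @export
write_brat_project <- function(corpus, dir, write_conllu = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (doc in corpus) {
    pair <- write_brat(doc)
    write_file_utf8(pair$text, file.path(dir, paste0(doc$doc_id, ".txt")))
    write_file_utf8(pair$ann, file.path(dir, paste0(doc$doc_id, ".ann")))
    if (write_conllu && nrow(doc$tokens) > 0)
      write_file_utf8(format_conllu(doc), file.path(dir, paste0(doc$doc_id, ".conllu")))
  }
  invisible(dir)
}

#' Load the NorSynthClinical corpus from a local checkout
#'
#' The synthetic Norwegian family-history corpus (GitHub
#' `ltgoslo/NorSynthClinical`) is distributed as a brat project with
#' parallel CoNLL-U files.  This loader reads any local checkout of it;
#' it performs no network access.
#'
#' @param dir path to the checkout.
#' @return A list of [fh_document()]s.
#' @export
load_norsynthclinical <- function(dir) {
  if (!dir.exists(dir)) stop("corpus directory not found: ", dir)
  read_brat_project(dir)
}

read_file_utf8 <- function(path) {
  raw <- readChar(path, file.info(path)$size, useBytes = TRUE)
  Encoding(raw) <- "UTF-8"
  raw
}

write_file_utf8 <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(enc2utf8(x), con, eos = NULL, useBytes = TRUE)
  invisible(path)
}
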