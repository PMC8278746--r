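#' Entity and relation inventories of the family-history annotation scheme
#'
#' The scheme distinguishes five *clinical* entity types (FAMILY, SELF,
#' INDEX, CONDITION, EVENT) and five *modifier* types (SIDE, AGE, NEG,
#' AMOUNT, TEMPORAL).  Token classification additionally uses the
#' out-label `"O"`, giving 11 classes in total.  Relations are binary and
#' directed: `Holder` links a CONDITION/EVENT to the person bearing it,
#' `Modifier` links a modifier entity to a clinical entity, and
#' `Related_to`, `Subset` and `Partner` link family members to each other.
#' `No_Relation` is the label given to candidate entity pairs with no
#' annotated relation.
#'
#' @return Character vectors of label names, in the package's canonical
#'   (fixed) order.
#' @export
entity_labels <- function() {
  c("FAMILY", "SELF", "INDEX", "CONDITION", "EVENT",
    "SIDE", "AGE", "NEG", "AMOUNT", "TEMPORAL")
}

#' @rdname entity_labels
#' @export
clinical_labels <- function() c("FAMILY", "SELF", "INDEX", "CONDITION", "EVENT")

#' @rdname entity_labels
#' @export
modifier_labels <- function() c("SIDE", "AGE", "NEG", "AMOUNT", "TEMPORAL")

#' @rdname entity_labels
#' @export
token_labels <- function() c(entity_labels(), "O")

#' @rdname entity_labels
#' @export
relation_labels <- function() {
  c("Holder", "Modifier", "Related_to", "Subset", "Partner", "No_Relation")
}

#' Construct the annotation-scheme constraint table
#'
#' Builds the permissibility constraints between relation labels and their
#' argument entity labels.  In `"permissive"` mode (the default) a
#' `Modifier` relation may target any clinical entity; `"strict"` mode
#' restricts SIDE modifiers to FAMILY targets and keeps `Related_to`
#' endpoints to FAMILY only.  `allow_self_related` extends
#' `Related_to`/`Subset` endpoints with SELF and INDEX, which some
#' annotated corpora use for statements like "her brother" where the
#' anchor is the patient.
#'
#' @param mode `"permissive"` or `"strict"`.
#' @param allow_self_related also admit SELF/INDEX as `Related_to`/`Subset`
#'   endpoints (default `FALSE`, honouring the guideline that these hold
#'   between Family entities).
#' @return An object of class `fh_schema`: a list with the label
#'   inventories and a per-relation table of allowed argument labels.
#' @export
fh_schema <- function(mode = c("permissive", "strict"), allow_self_related = FALSE) {
  mode <- match.arg(mode)
  persons <- c("FAMILY", "SELF", "INDEX")
  fam <- if (allow_self_related) persons else "FAMILY"
  constraints <- list(
    Holder     = list(arg1 = c("CONDITION", "EVENT"), arg2 = persons),
    Modifier   = list(arg1 = modifier_labels(),       arg2 = clinical_labels()),
    Related_to = list(arg1 = fam, arg2 = fam),
    Subset     = list(arg1 = fam, arg2 = fam),
    Partner    = list(arg1 = fam, arg2 = fam)
  )
  if (mode == "strict") {
    # SIDE describes the side of the family and modifies FAMILY entities only
    constraints$SIDE_target <- "FAMILY"
  }
  structure(
    list(mode = mode, allow_self_related = allow_self_related,
         entity_labels = entity_labels(), relation_labels = relation_labels(),
         constraints = constraints),
    class = "fh_schema"
  )
}

#' @export
print.fh_schema <- function(x, ...) {
  cat("<fh_schema> mode:", x$mode, "\n")
  for (r in setdiff(x$relation_labels, "No_Relation")) {
    con <- x$constraints[[r]]
    cat(sprintf("  %-10s arg1: {%s}  arg2: {%s}\n", r,
                paste(con$arg1, collapse = ","), paste(con$arg2, collapse = ",")))
  }
  invisible(x)
}

#' Is a relation permitted between two entity labels?
#'
#' @param relation a relation label (one of [relation_labels()]).
#' @param arg1,arg2 entity labels of the first and second argument.
#' @param schema an [fh_schema()] object.
#' @return `TRUE` iff the relation/argument combination is allowed by the
#'   scheme.  `No_Relation` is always allowed.
#' @examples
#' allowed_relation("Holder", "CONDITION", "FAMILY")  # TRUE
#' allowed_relation("Partner", "CONDITION", "FAMILY") # FALSE
#' @export
allowed_relation <- function(relation, arg1, arg2, schema = fh_schema()) {
  if (!relation %in% schema$relation_labels)
    stop("unknown relation label: ", relation)
  for (a in c(arg1, arg2))
    if (!a %in% schema$entity_labels) stop("unknown entity label: ", a)
  if (relation == "No_Relation") return(TRUE)
  con <- schema$constraints[[relation]]
  ok <- arg1 %in% con$arg1 && arg2 %in% con$arg2
  if (ok && relation == "Modifier" && !is.null(schema$constraints$SIDE_target) &&
      arg1 == "SIDE") {
    ok <- arg2 %in% schema$constraints$SIDE_target
  }
  ok
}

#' Validate a document against the annotation scheme
#'
#' Checks entity spans against the text bounds, flags overlapping entity
#' pairs, dangling relation arguments, and relations whose argument labels
#' are not permitted by the scheme.  Violations are returned as data, not
#' raised as errors: overlapping spans in particular are legal brat output
#' and are resolved later during token projection.
#'
#' @param doc an `fh_document`.
#' @param schema an [fh_schema()].
#' @return A data frame with columns `type`, `id` and `message`; zero rows
#'   mean the document conforms to the scheme.
#' @export
validate_document <- function(doc, schema = fh_schema()) {
  stopifnot(inherits(doc, "fh_document"))
  v <- list()
  add <- function(type, id, message) {
    v[[length(v) + 1L]] <<- data.frame(type = type, id = id, message = message)
  }
  ents <- doc$entities
  n <- nrow(ents)
  nchar_text <- nchar(doc$text)
  if (n > 0) {
    for (i in seq_len(n)) {
      if (ents$start[i] < 0 || ents$end[i] > nchar_text || ents$start[i] >= ents$end[i])
        add("span_bounds", ents$id[i],
            sprintf("entity %s [%d,%d) outside text of %d characters",
                    ents$id[i], ents$start[i], ents$end[i], nchar_text))
      if (!ents$label[i] %in% entity_labels())
        add("entity_label", ents$id[i], paste("unknown entity label", ents$label[i]))
    }
    if (n > 1) {
      ord <- order(ents$start, ents$end)
      for (a in seq_len(n - 1)) for (b in seq(a + 1, n)) {
        i <- ord[a]; j <- ord[b]
        if (ents$start[j] < ents$end[i])
          add("overlap", paste(ents$id[i], ents$id[j]),
              sprintf("entities %s and %s overlap", ents$id[i], ents$id[j]))
      }
    }
  }
  rels <- doc$relations
  if (nrow(rels) > 0) {
    for (i in seq_len(nrow(rels))) {
      a1 <- match(rels$arg1[i], ents$id)
      a2 <- match(rels$arg2[i], ents$id)
      if (is.na(a1) || is.na(a2)) {
        add("dangling_argument", rels$id[i],
            sprintf("relation %s refers to missing entity", rels$id[i]))
        next
      }
      if (!rels$label[i] %in% schema$relation_labels) {
        add("relation_label", rels$id[i], paste("unknown relation label", rels$label[i]))
        next
      }
      if (!allowed_relation(rels$label[i], ents$label[a1], ents$label[a2], schema))
        add("relation_constraint", rels$id[i],
            sprintf("%s(%s -> %s) violates the %s constraint",
                    rels$label[i], ents$label[a1], ents$label[a2], rels$label[i]))
    }
  }
  if (length(v) == 0)
    return(data.frame(type = character(), id = character(), message = character()))
  do.call(rbind, v)
}

#' Serialize / restore a schema as a plain YAML config
#'
#' @param schema an [fh_schema()].
#' @param path file to write / read.
#' @return `read_schema` returns an `fh_schema`.
#' @export
write_schema <- function(schema, path) {
  out <- list(
    mode = schema$mode,
    allow_self_related = schema$allow_self_related,
    entity_labels = schema$entity_labels,
    relation_labels = schema$relation_labels,
    constraints = lapply(
      schema$constraints[setdiff(names(schema$constraints), "SIDE_target")],
      function(x) list(arg1 = x$arg1, arg2 = x$arg2))
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  fh_schema(mode = raw$mode, allow_self_related = isTRUE(raw$allow_self_related))
}
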