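#' Built-in cellular compartment definitions
#'
#' The ten canonical compartments used throughout the package and their
#' root GO cellular-component terms. The four "major" compartments
#' (nucleus, cytoplasm, mitochondrion, extracellular) typically cover the
#' bulk of annotated proteins and are the default analysis set.
#'
#' @param set `"ten"` (default), `"four"` for the four major compartments,
#'   or a character vector of compartment names to subset.
#' @return Named list mapping compartment name to character vector of root
#'   GO term ids.
#' @export
compartment_definitions <- function(set = "ten") {
  defs <- list(
    nucleus               = "GO:0005634",
    cytoplasm             = "GO:0005737",
    mitochondrion         = "GO:0005739",
    extracellular         = c("GO:0005576", "GO:0031012", "GO:0044421", "GO:0044420"),
    peroxisome            = "GO:0005777",
    lysosome              = "GO:0005764",
    endoplasmic_reticulum = "GO:0005783",
    golgi_apparatus       = "GO:0005794",
    cell_membrane         = "GO:0005886",
    nuclear_membrane      = "GO:0031965"
  )
  four <- c("nucleus", "cytoplasm", "mitochondrion", "extracellular")
  if (identical(set, "ten")) return(defs)
  if (identical(set, "four")) return(defs[four])
  unknown <- setdiff(set, names(defs))
  if (length(unknown))
    stop("unknown compartment(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  defs[set]
}

#' Parse an OBO ontology file into a child-to-parent graph
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas and returns the directed acyclic
#' child -> parent graph of the cellular_component namespace (or all
#' namespaces if none is declared), following `is_a` and
#' `relationship: part_of` edges. Obsolete terms are excluded.
#'
#' @param obo_path Path to the OBO file (optionally gzipped).
#' @param namespace Namespace to keep; default `"cellular_component"`.
#'   Terms without a namespace line are kept.
#' @return An object of class `"ontology_graph"`: list with `parents`
#'   (named list: term id -> character vector of parent ids) and `terms`
#'   (all term ids).
#' @export
parse_ontology <- function(obo_path, namespace = "cellular_component") {
  lines <- readLines(gzfile(obo_path), warn = FALSE)
  starts <- grep("^\\[", lines)
  if (!length(starts))
    stop("malformed OBO (no stanzas found): ", obo_path, call. = FALSE)
  term_starts <- starts[lines[starts] == "[Term]"]
  bounds <- c(starts, length(lines) + 1L)
  parents <- list()
  keep_ns <- character()
  for (s in term_starts) {
    e <- bounds[which(bounds == s) + 1L] - 1L
    block <- lines[(s + 1L):e]
    id <- sub("^id: *", "", grep("^id: ", block, value = TRUE))
    if (length(id) != 1L)
      stop(sprintf("malformed OBO stanza at line %d: expected exactly one id", s),
           call. = FALSE)
    id <- trimws(id)
    if (any(grepl("^is_obsolete: *true", block))) next
    ns <- sub("^namespace: *", "", grep("^namespace: ", block, value = TRUE))
    if (length(ns) == 1L && !is.null(namespace) && trimws(ns) != namespace) next
    isa <- sub("^is_a: *([^ !]+).*", "\\1", grep("^is_a: ", block, value = TRUE))
    po <- grep("^relationship: *part_of ", block, value = TRUE)
    po <- sub("^relationship: *part_of *([^ !]+).*", "\\1", po)
    parents[[id]] <- unique(trimws(c(isa, po)))
  }
  terms <- names(parents)
  # drop edges that point outside the retained namespace
  parents <- lapply(parents, function(p) intersect(p, terms))
  g <- structure(list(parents = parents, terms = terms), class = "ontology_graph")
  if (has_cycle(g))
    stop("cyclic is_a/part_of relations in ontology", call. = FALSE)
  g
}

has_cycle <- function(g) {
  state <- new.env(parent = emptyenv())
  visit <- function(id) {
    st <- state[[id]]
    if (identical(st, 1L)) return(TRUE)   # on current path
    if (identical(st, 2L)) return(FALSE)
    state[[id]] <- 1L
    for (p in g$parents[[id]]) if (visit(p)) return(TRUE)
    state[[id]] <- 2L
    FALSE
  }
  for (id in g$terms) if (visit(id)) return(TRUE)
  FALSE
}

#' Collect a set of root terms together with all their offspring
#'
#' Returns the given roots plus every term from which a root is reachable
#' by child -> parent (`is_a`/`part_of`) edges, i.e. the offspring closure
#' used to expand each compartment's root term(s).
#'
#' @param graph An `"ontology_graph"` from [parse_ontology()].
#' @param roots Character vector of root term ids; must be present in the
#'   graph.
#' @return Character vector of term ids (roots plus offspring, each once).
#' @export
collect_offspring <- function(graph, roots) {
  stopifnot(inherits(graph, "ontology_graph"))
  absent <- setdiff(roots, graph$terms)
  if (length(absent))
    stop("root term(s) absent from ontology: ",
         paste(absent, collapse = ", "), call. = FALSE)
  # invert to parent -> children once, then BFS down from the roots
  child_of <- new.env(parent = emptyenv())
  for (id in graph$terms)
    for (p in graph$parents[[id]])
      child_of[[p]] <- c(child_of[[p]], id)
  seen <- new.env(parent = emptyenv())
  queue <- unique(roots)
  for (r in queue) seen[[r]] <- TRUE
  while (length(queue)) {
    id <- queue[[1L]]
    queue <- queue[-1L]
    for (ch in child_of[[id]]) {
      if (is.null(seen[[ch]])) {
        seen[[ch]] <- TRUE
        queue <- c(queue, ch)
      }
    }
  }
  sort(ls(seen))
}

#' Expand compartment definitions over an ontology
#'
#' @param graph An `"ontology_graph"`.
#' @param defs Named list of root term ids per compartment, as returned by
#'   [compartment_definitions()].
#' @return Named list of expanded term sets (roots plus offspring).
#' @export
expand_compartments <- function(graph, defs) {
  lapply(defs, function(roots) collect_offspring(graph, roots))
}

#' Read a GAF protein-to-GO annotation file
#'
#' Parses GAF 2.1/2.2: column 2 is the protein (DB object) id, column 4
#' the qualifier, column 5 the GO id, column 7 the evidence code. Rows with
#' a `NOT` qualifier are skipped. Evidence codes are not filtered by
#' default.
#'
#' @param path Path to the GAF file (optionally gzipped).
#' @param evidence Optional character vector of evidence codes to keep
#'   (e.g. experimental codes); `NULL` keeps all.
#' @return Named list: protein id -> character vector of GO term ids.
#' @export
read_gaf <- function(path, evidence = NULL) {
  lines <- readLines(gzfile(path), warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) stop("no annotation rows in GAF file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 7L)
  if (length(bad))
    stop("malformed GAF row (fewer than 7 columns) at data line ", bad[1L],
         call. = FALSE)
  ids <- vapply(fields, `[[`, "", 2L)
  qual <- vapply(fields, `[[`, "", 4L)
  go <- vapply(fields, `[[`, "", 5L)
  ev <- vapply(fields, `[[`, "", 7L)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
  if (!is.null(evidence)) keep <- keep & ev %in% evidence
  split(go[keep], ids[keep])
}

#' Assign proteins to compartments from their GO terms
#'
#' A protein is assigned to a compartment when its GO term set intersects
#' the compartment's expanded term set. Secondary identifiers (isoform
#' suffixes such as `P12345-2`) can be merged into their primary accession
#' before matching, in which case term sets are unioned.
#'
#' @param protein_terms Named list: protein id -> character vector of GO
#'   term ids (e.g. from [read_gaf()]).
#' @param expanded_defs Named list of expanded term sets per compartment
#'   (from [expand_compartments()], or raw roots for a strict match).
#' @param strip_isoforms Logical; strip `-N` isoform suffixes from protein
#'   ids and merge term sets (default `FALSE`).
#' @return An object of class `"compartment_annotation"`: list with
#'   `compartments` (named list: protein id -> character vector of
#'   compartment names, possibly empty) and `provenance` (`"go"`).
#' @export
assign_compartments <- function(protein_terms, expanded_defs, strip_isoforms = FALSE) {
  if (strip_isoforms) {
    ids <- sub("-[0-9]+$", "", names(protein_terms))
    protein_terms <- lapply(split(protein_terms, ids),
                            function(x) unique(unlist(x, use.names = FALSE)))
  }
  comp_names <- names(expanded_defs)
  assignments <- lapply(protein_terms, function(terms) {
    comp_names[vapply(expanded_defs, function(s) any(terms %in% s), logical(1L))]
  })
  structure(list(compartments = assignments, provenance = "go"),
            class = "compartment_annotation")
}

#' @export
print.compartment_annotation <- function(x, ...) {
  n <- length(x$compartments)
  k <- lengths(x$compartments)
  cat(sprintf("compartment_annotation (%s): %d proteins, %d annotated to >=1 compartment\n",
              x$provenance, n, sum(k > 0L)))
  invisible(x)
}

#' Restrict an annotation to compartment-exclusive proteins
#'
#' Keeps only proteins annotated to exactly one compartment within the
#' given set. Used for the model-robustness comparison of all-protein vs
#' exclusive-protein compartment models.
#'
#' @param ann A `"compartment_annotation"`.
#' @param compartments Compartment names considered; defaults to all names
#'   present in the annotation.
#' @return A `"compartment_annotation"` containing only exclusive proteins.
#' @export
restrict_exclusive <- function(ann, compartments = NULL) {
  stopifnot(inherits(ann, "compartment_annotation"))
  sets <- ann$compartments
  if (!is.null(compartments))
    sets <- lapply(sets, function(s) intersect(s, compartments))
  keep <- lengths(sets) == 1L
  structure(list(compartments = sets[keep], provenance = ann$provenance),
            class = "compartment_annotation")
}

#' Load a custom protein grouping as a compartment annotation
#'
#' Reads a two-column table (protein, group). Groups behave exactly like
#' compartments downstream, enabling curated organelle catalogues
#' (MitoCarta-style) or protein-complex groupings.
#'
#' @param path Path to a two-column TSV/CSV (header optional: detected when
#'   the first row is `protein<sep>group`).
#' @return A `"compartment_annotation"` with provenance `"custom"`.
#' @export
load_custom_groups <- function(path) {
  lines <- readLines(gzfile(path), warn = FALSE)
  blank <- !nzchar(trimws(lines))
  if (any(blank)) {
    warning(sum(blank), " blank line(s) skipped in ", path, call. = FALSE)
    lines <- lines[!blank]
  }
  if (!length(lines)) stop("empty grouping file: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("grouping file must have two columns (protein, group): ", path,
         call. = FALSE)
  prot <- trimws(vapply(fields, `[[`, "", 1L))
  grp <- trimws(vapply(fields, `[[`, "", 2L))
  if (tolower(prot[[1L]]) %in% c("protein", "protein_id", "id") ) {
    prot <- prot[-1L]; grp <- grp[-1L]
  }
  if (!length(prot)) stop("empty grouping file: ", path, call. = FALSE)
  structure(list(compartments = lapply(split(grp, prot), unique),
                 provenance = "custom"),
            class = "compartment_annotation")
}

#' Build a compartment annotation from a named list
#'
#' Convenience constructor for programmatic use (and the synthetic-data
#' generator): a named list mapping protein id to a character vector of
#' compartment/group names.
#'
#' @param x Named list: protein id -> character vector of names.
#' @param provenance `"custom"` (default) or `"go"`.
#' @return A `"compartment_annotation"`.
#' @export
as_compartment_annotation <- function(x, provenance = "custom") {
  stopifnot(is.list(x), !is.null(names(x)))
  structure(list(compartments = lapply(x, as.character), provenance = provenance),
            class = "compartment_annotation")
}

#' Summarize annotation coverage of a protein set
#'
#' Fractions of the given proteins annotated to: nothing, any GO
#' cellular-component term, at least one of the ten compartments, and at
#' least one of the four major compartments.
#'
#' @param protein_ids Character vector of quantified proteins.
#' @param ann A `"compartment_annotation"` over the ten compartments.
#' @param protein_terms Optional named list of raw GO term sets (to compute
#'   the "any CC term" category); when `NULL` that category equals the
#'   ten-compartment one.
#' @return Data frame with columns `category`, `n`, `fraction`.
#' @export
annotation_coverage_summary <- function(protein_ids, ann, protein_terms = NULL) {
  stopifnot(inherits(ann, "compartment_annotation"))
  four <- names(compartment_definitions("four"))
  sets <- ann$compartments[protein_ids]
  sets[vapply(sets, is.null, logical(1L))] <- list(character())
  n_any_cc <- if (is.null(protein_terms)) {
    sum(lengths(sets) > 0L)
  } else {
    sum(lengths(protein_terms[protein_ids]) > 0L, na.rm = TRUE)
  }
  n_ten <- sum(lengths(sets) > 0L)
  n_four <- sum(vapply(sets, function(s) any(s %in% four), logical(1L)))
  n <- length(protein_ids)
  data.frame(
    category = c("unannotated", "any_cc_term", "ten_compartments", "four_major"),
    n = c(n - n_any_cc, n_any_cc, n_ten, n_four),
    fraction = c(n - n_any_cc, n_any_cc, n_ten, n_four) / n,
    stringsAsFactors = FALSE
  )
}

#' Proteins annotated to a given compartment
#' @param ann A `"compartment_annotation"`.
#' @param compartment Compartment name.
#' @return Character vector of protein ids.
#' @export
compartment_members <- function(ann, compartment) {
  names(ann$compartments)[vapply(ann$compartments,
                                 function(s) compartment %in% s, logical(1L))]
}
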