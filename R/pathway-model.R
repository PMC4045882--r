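#' Default list of ubiquitous ("currency") compounds
#'
#' Compounds such as water, ATP or NAD participate in very many reactions and
#' would create spurious connectivity in the hypergraph, so they are excluded
#' from the compound nodes at build time. The default list covers the usual
#' currency metabolites by KEGG compound id; pass your own character vector to
#' [build_hypergraph()] to override it.
#'
#' @return Character vector of KEGG compound ids.
#' @export
kegg_ubiquitous_compounds <- function() {
  c(
    "C00001", # H2O
    "C00002", # ATP
    "C00008", # ADP
    "C00020", # AMP
    "C00003", # NAD+
    "C00004", # NADH
    "C00006", # NADP+
    "C00005", # NADPH
    "C00009", # orthophosphate
    "C00013", # diphosphate
    "C00011", # CO2
    "C00007", # O2
    "C00080", # H+
    "C00010"  # CoA
  )
}

#' Create a raw reaction record
#'
#' A raw record is the pre-expansion form of a reaction, as read from KGML or
#' pathway JSON: it still carries its reversibility flag and its compound
#' lists have not been filtered for ubiquitous compounds.
#'
#' @param id Reaction identifier (non-empty string).
#' @param inputs Character vector of substrate compound ids.
#' @param outputs Character vector of product compound ids.
#' @param ec Character vector of EC numbers (may be empty).
#' @param reversible Logical flag.
#' @return A list with class `reaction_record`.
#' @export
reaction_record <- function(id, inputs = character(), outputs = character(),
                            ec = character(), reversible = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("reaction record needs a non-empty character id")
  }
  structure(
    list(id = id,
         inputs = unique(as.character(inputs)),
         outputs = unique(as.character(outputs)),
         ec = as.character(ec),
         reversible = isTRUE(reversible)),
    class = "reaction_record"
  )
}

new_reaction <- function(id, inputs, outputs, ec, reversible, is_backward) {
  structure(
    list(id = id,
         inputs = unique(as.character(inputs)),
         outputs = unique(as.character(outputs)),
         ec = as.character(ec),
         reversible = isTRUE(reversible),
         is_backward = isTRUE(is_backward)),
    class = "pathway_reaction"
  )
}

#' Expand a reversible record into directed hyperedges
#'
#' An irreversible record yields a single forward reaction. A reversible
#' record yields the forward reaction plus a backward copy with inputs and
#' outputs swapped, whose id is the forward id with the suffix `"rev"`.
#'
#' @param record A [reaction_record()].
#' @return List of one or two `pathway_reaction` objects.
#' @export
expand_reversible <- function(record) {
  stopifnot(inherits(record, "reaction_record"))
  fwd <- new_reaction(record$id, record$inputs, record$outputs,
                      record$ec, record$reversible, is_backward = FALSE)
  if (!record$reversible) {
    return(list(fwd))
  }
  bwd <- new_reaction(paste0(record$id, "rev"), record$outputs, record$inputs,
                      record$ec, reversible = TRUE, is_backward = TRUE)
  list(fwd, bwd)
}

#' Build the directed-hypergraph representation of a pathway
#'
#' Compounds are nodes and reactions are directed hyperedges R = (I, E, O)
#' linking substrate set I to product set O, with the catalysing enzymes E
#' kept as a reaction attribute. Ubiquitous compounds are removed from all
#' substrate and product sets, reversible records are expanded into a forward
#' and a backward hyperedge, and reactions left with no compounds on either
#' side after filtering are dropped.
#'
#' @param records List of [reaction_record()] objects.
#' @param ubiquitous Character vector of compound ids to exclude
#'   (default [kegg_ubiquitous_compounds()]).
#' @param id Pathway identifier.
#' @return A `pathway_hypergraph` object.
#' @export
build_hypergraph <- function(records, ubiquitous = kegg_ubiquitous_compounds(),
                             id = "pathway") {
  stopifnot(is.list(records))
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate reaction id: ", ids[duplicated(ids)][1])
  }
  reactions <- list()
  for (rec in records) {
    if (!inherits(rec, "reaction_record")) {
      rec <- reaction_record(rec$id, rec$inputs, rec$outputs,
                             rec$ec %||% character(), isTRUE(rec$reversible))
    }
    if (length(rec$inputs) == 0L && length(rec$outputs) == 0L) {
      stop("reaction ", rec$id, " has no compounds at all")
    }
    rec$inputs <- setdiff(rec$inputs, ubiquitous)
    rec$outputs <- setdiff(rec$outputs, ubiquitous)
    if (length(rec$inputs) == 0L && length(rec$outputs) == 0L) {
      next  # hyperedge with no endpoints left: drop
    }
    for (rx in expand_reversible(rec)) {
      reactions[[rx$id]] <- rx
    }
  }
  h <- structure(
    list(id = id,
         reactions = reactions,
         compounds = sort(unique(as.character(unlist(lapply(reactions, function(r)
           c(r$inputs, r$outputs)))))),
         ubiquitous_filter = as.character(ubiquitous)),
    class = "pathway_hypergraph"
  )
  validate_hypergraph(h)
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a pathway hypergraph
#'
#' Checks reaction-id uniqueness, that every compound referenced by a
#' reaction appears in the compound set, and that every backward copy has a
#' forward twin with swapped substrate/product sets.
#'
#' @param h A `pathway_hypergraph`.
#' @return `h`, invisibly; stops on violation.
#' @export
validate_hypergraph <- function(h) {
  stopifnot(inherits(h, "pathway_hypergraph"))
  ids <- names(h$reactions)
  if (anyDuplicated(ids)) stop("duplicate reaction id in hypergraph")
  for (r in h$reactions) {
    if (length(r$inputs) == 0L && length(r$outputs) == 0L) {
      stop("reaction ", r$id, " has no endpoints")
    }
    missing <- setdiff(c(r$inputs, r$outputs), h$compounds)
    if (length(missing)) {
      stop("reaction ", r$id, " references unknown compound ", missing[1])
    }
    if (r$is_backward) {
      fid <- sub("rev$", "", r$id)
      fwd <- h$reactions[[fid]]
      if (!is.null(fwd) &&
          (!setequal(fwd$inputs, r$outputs) || !setequal(fwd$outputs, r$inputs))) {
        stop("backward copy ", r$id, " is not the mirror of ", fid)
      }
    }
  }
  invisible(h)
}

#' @export
print.pathway_hypergraph <- function(x, ...) {
  cat("pathway_hypergraph '", x$id, "': ",
      length(x$reactions), " reactions, ",
      length(x$compounds), " compounds\n", sep = "")
  invisible(x)
}

#' Classify compounds as sources, sinks or internal
#'
#' Source metabolites appear only as reaction inputs (they are produced by
#' other pathways), sinks only as outputs, and internal compounds are both
#' produced and consumed within the pathway. The three sets partition the
#' compounds referenced by at least one reaction.
#'
#' @param h A `pathway_hypergraph`.
#' @return List with sorted character vectors `sources`, `sinks`, `internal`.
#' @export
classify_compounds <- function(h) {
  stopifnot(inherits(h, "pathway_hypergraph"))
  ins <- unique(unlist(lapply(h$reactions, `[[`, "inputs")))
  outs <- unique(unlist(lapply(h$reactions, `[[`, "outputs")))
  list(sources = sort(setdiff(ins, outs)),
       sinks = sort(setdiff(outs, ins)),
       internal = sort(intersect(ins, outs)))
}

# ---- plain JSON pathway format ----------------------------------------------

#' Write a pathway to JSON
#'
#' Serializes a built hypergraph. The file carries `"expanded": true` so the
#' reader restores it verbatim (same ids, substrate/product sets, enzymes)
#' without re-filtering or re-expanding.
#'
#' @param h A `pathway_hypergraph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pathway_json <- function(h, path) {
  stopifnot(inherits(h, "pathway_hypergraph"))
  obj <- list(
    id = h$id,
    expanded = TRUE,
    ubiquitous_filter = h$ubiquitous_filter,
    reactions = lapply(unname(h$reactions), function(r) {
      list(id = r$id, inputs = r$inputs, outputs = r$outputs,
           ec = r$ec, reversible = r$reversible, is_backward = r$is_backward)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a pathway from JSON
#'
#' Accepts two dialects: the serialized form written by
#' [write_pathway_json()] (`"expanded": true`, restored verbatim), and the
#' plain input format `{"id", "reactions": [{"id", "inputs", "outputs",
#' "ec", "reversible"}]}`, which is run through [build_hypergraph()] with the
#' given ubiquitous list.
#'
#' @param path JSON file path.
#' @param ubiquitous Ubiquitous-compound list applied to the plain format.
#' @return A `pathway_hypergraph`.
#' @export
read_pathway_json <- function(path, ubiquitous = kegg_ubiquitous_compounds()) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (isTRUE(obj$expanded)) {
    reactions <- list()
    for (r in obj$reactions) {
      rx <- new_reaction(r$id, unlist(r$inputs) %||% character(),
                         unlist(r$outputs) %||% character(),
                         unlist(r$ec) %||% character(),
                         isTRUE(r$reversible), isTRUE(r$is_backward))
      reactions[[rx$id]] <- rx
    }
    h <- structure(
      list(id = obj$id,
           reactions = reactions,
           compounds = sort(unique(as.character(unlist(lapply(reactions, function(r)
             c(r$inputs, r$outputs)))))),
           ubiquitous_filter = as.character(unlist(obj$ubiquitous_filter) %||%
                                              character())),
      class = "pathway_hypergraph"
    )
    return(validate_hypergraph(h))
  }
  records <- lapply(obj$reactions, function(r) {
    reaction_record(r$id, unlist(r$inputs) %||% character(),
                    unlist(r$outputs) %||% character(),
                    unlist(r$ec) %||% character(), isTRUE(r$reversible))
  })
  build_hypergraph(records, ubiquitous = ubiquitous,
                   id = obj$id %||% "pathway")
}

# ---- KGML -------------------------------------------------------------------

strip_kegg_prefix <- function(x) sub("^[a-z]+:", "", x)

#' Parse a KGML (KEGG XML) pathway file into raw reaction records
#'
#' Reads the `<reaction>` elements with their `<substrate>`/`<product>`
#' children and resolves EC numbers from enzyme/ortholog/gene `<entry>`
#' elements whose `reaction` attribute names the reaction. KEGG prefixes
#' (`cpd:`, `rn:`, `ec:`) are stripped. Reactions lacking both substrates and
#' products are skipped with a warning.
#'
#' @param path KGML file path (or a literal XML string).
#' @return List of [reaction_record()] objects; pathway name in
#'   attribute `"pathway_id"`.
#' @export
parse_kgml <- function(path) {
  doc <- xml2::read_xml(path)
  pathway_id <- strip_kegg_prefix(xml2::xml_attr(doc, "name") %||% "pathway")
  if (is.na(pathway_id)) pathway_id <- "pathway"

  # EC numbers attached to reactions via enzyme-like entries
  entries <- xml2::xml_find_all(
    doc, ".//entry[@type='enzyme' or @type='ortholog' or @type='gene']")
  ec_by_reaction <- list()
  for (e in entries) {
    rxns <- xml2::xml_attr(e, "reaction")
    nm <- xml2::xml_attr(e, "name")
    if (is.na(rxns) || is.na(nm)) next
    ecs <- grep("^ec:", strsplit(nm, "\\s+")[[1]], value = TRUE)
    if (!length(ecs)) next
    for (rid in strip_kegg_prefix(strsplit(rxns, "\\s+")[[1]])) {
      ec_by_reaction[[rid]] <- unique(c(ec_by_reaction[[rid]],
                                        strip_kegg_prefix(ecs)))
    }
  }

  records <- list()
  for (rx in xml2::xml_find_all(doc, ".//reaction")) {
    rid <- strip_kegg_prefix(xml2::xml_attr(rx, "name"))
    subs <- strip_kegg_prefix(
      xml2::xml_attr(xml2::xml_find_all(rx, "./substrate"), "name"))
    prods <- strip_kegg_prefix(
      xml2::xml_attr(xml2::xml_find_all(rx, "./product"), "name"))
    if (length(subs) == 0L && length(prods) == 0L) {
      warning("KGML reaction ", rid, " has no substrates or products; skipped")
      next
    }
    records[[length(records) + 1L]] <- reaction_record(
      id = rid, inputs = subs, outputs = prods,
      ec = ec_by_reaction[[rid]] %||% character(),
      reversible = identical(xml2::xml_attr(rx, "type"), "reversible"))
  }
  attr(records, "pathway_id") <- pathway_id
  records
}

#' Read a pathway file of either supported format
#'
#' Dispatches on file extension: `.xml`/`.kgml` through [parse_kgml()] and
#' [build_hypergraph()], `.json` through [read_pathway_json()].
#'
#' @param path Pathway file.
#' @param ubiquitous Ubiquitous-compound list for formats that need building.
#' @return A `pathway_hypergraph`.
#' @export
read_pathway <- function(path, ubiquitous = kegg_ubiquitous_compounds()) {
  if (!file.exists(path)) stop("pathway file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xml", "kgml")) {
    records <- parse_kgml(path)
    build_hypergraph(records, ubiquitous = ubiquitous,
                     id = attr(records, "pathway_id"))
  } else if (ext == "json") {
    read_pathway_json(path, ubiquitous = ubiquitous)
  } else {
    stop("unsupported pathway format: .", ext)
  }
}
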