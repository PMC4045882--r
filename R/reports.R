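# Report writers for alignment results.

style_rev <- function(ids, rev_style) {
  if (identical(rev_style, "#rev")) sub("rev$", "#rev", ids) else ids
}

#' Write the path-alignment report
#'
#' For each matched path pair, a `Score:` line followed by the aligned
#' columns, tab-separated, with `-` for gaps.
#'
#' @param result A `pathway_alignment`.
#' @param path Output file.
#' @param rev_style `"rev"` or `"#rev"` id dialect.
#' @return `path`, invisibly.
#' @export
write_path_alignment_report <- function(result, path, rev_style = "rev") {
  stopifnot(inherits(result, "pathway_alignment"))
  lines <- c(paste0("Path alignment ", result$h1_id, "-", result$h2_id))
  sig <- result$sigma
  for (k in seq_len(nrow(sig))) {
    al <- result$alignments[[paste(sig$left[k], sig$right[k])]]
    lines <- c(lines, paste0("Score: ", format(al$score, digits = 12)))
    cols <- al$columns
    l <- ifelse(is.na(cols$left), "-", style_rev(cols$left, rev_style))
    r <- ifelse(is.na(cols$right), "-", style_rev(cols$right, rev_style))
    lines <- c(lines, paste(l, r, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the reaction-matching TSV
#'
#' Two columns: reaction of pathway 1, matched reaction of pathway 2.
#'
#' @inheritParams write_path_alignment_report
#' @return `path`, invisibly.
#' @export
write_reaction_matching_tsv <- function(result, path, rev_style = "rev") {
  stopifnot(inherits(result, "pathway_alignment"))
  tab <- data.frame(reaction1 = style_rev(result$rho$left, rev_style),
                    reaction2 = style_rev(result$rho$right, rev_style),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the final-alignment TSV (conserved subpathway)
#'
#' Columns: conserved reaction of pathway 1, its matched image, and the
#' enzyme(s) of the pathway-1 reaction.
#'
#' @param h1 The first `pathway_hypergraph` (for enzyme annotation).
#' @inheritParams write_path_alignment_report
#' @return `path`, invisibly.
#' @export
write_final_alignment_tsv <- function(result, h1, path, rev_style = "rev") {
  stopifnot(inherits(result, "pathway_alignment"))
  cons <- result$conserved
  enzymes <- vapply(cons$reaction1, function(rid) {
    paste(h1$reactions[[rid]]$ec, collapse = ",")
  }, character(1))
  tab <- data.frame(reaction1 = style_rev(cons$reaction1, rev_style),
                    reaction2 = style_rev(cons$reaction2, rev_style),
                    enzyme = unname(enzymes),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the score report JSON
#'
#' Summary object: `score`, `distance`, path counts, number of matched
#' reactions, conserved-subpathway size and any diagnostic flags.
#'
#' @inheritParams write_path_alignment_report
#' @return `path`, invisibly.
#' @export
write_score_json <- function(result, path) {
  stopifnot(inherits(result, "pathway_alignment"))
  obj <- list(pathway1 = result$h1_id,
              pathway2 = result$h2_id,
              score = result$score,
              distance = result$distance,
              n_paths_1 = length(result$paths1),
              n_paths_2 = length(result$paths2),
              n_matched_reactions = nrow(result$rho),
              conserved_size = nrow(result$conserved),
              diagnostics = I(result$diagnostics))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
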