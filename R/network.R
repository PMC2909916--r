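# Assembly of typed regulatory edges and feedback / feed-forward motifs.
#
# Edge semantics are qualitative (presence/absence). "AP-1" is modelled as
# a factor node whose gene-level proxies are JUN and FOS; the ligand gene
# (interferon gamma) is a plain node with only incoming miRNA edges.

#' TF -> miRNA regulatory edges
#'
#' An edge (TF, miRNA) exists iff the miRNA's called promoter region
#' overlaps (>= 1 bp) a ChIP-enriched region that contains at least one
#' binding instance of that factor; multiplicity is the instance count in
#' the overlapping regions.
#'
#' @param promoter_calls data frame with `mirna_id`, `chrom`,
#'   `region_start`, `region_end` for accepted promoters
#' @param chip_regions [genomic_intervals()] of ChIP-enriched regions
#' @param instances instance data frame from [call_instances()] (column
#'   `tf`, `region_idx` indexing `chip_regions`), possibly several factors
#'   concatenated
#' @return edge data frame (`source`, `target`, `edge_type`, `multiplicity`)
#' @export
tf_to_mirna_edges <- function(promoter_calls, chip_regions, instances) {
  empty <- data.frame(source = character(), target = character(),
                      edge_type = character(), multiplicity = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(promoter_calls) || !nrow(chip_regions) || !nrow(instances)) {
    return(empty)
  }
  rows <- list()
  for (i in seq_len(nrow(promoter_calls))) {
    p <- promoter_calls[i, ]
    ov <- which(chip_regions$chrom == p$chrom &
                  chip_regions$start < p$region_end &
                  chip_regions$end > p$region_start)
    if (!length(ov)) next
    inst <- instances[instances$region_idx %in% ov, , drop = FALSE]
    if (!nrow(inst)) next
    cnt <- table(inst$tf)
    rows[[length(rows) + 1L]] <- data.frame(
      source = names(cnt), target = p$mirna_id,
      edge_type = "tf_regulates_mirna", multiplicity = as.integer(cnt),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' TF -> gene promoter-binding edges
#'
#' An edge exists iff a ChIP-enriched region overlaps the strand-aware
#' regulatory window (default -1000..+500 bp) around the gene's TSS.
#'
#' @param genes annotation data frame with `id`, `chrom`, `tss`, `strand`
#' @param chip_regions [genomic_intervals()] of ChIP-enriched regions
#' @param tf factor name attached as edge source
#' @param window regulatory window around the TSS, strand-oriented bp
#'   (default `c(-1000, 500)`)
#' @return edge data frame (`source`, `target`, `edge_type`, `multiplicity`)
#' @export
tf_to_gene_edges <- function(genes, chip_regions, tf = "TF",
                             window = c(-1000, 500)) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$strand == "-") {
      ws <- g$tss - window[2]
      we <- g$tss - window[1] + 1
    } else {
      ws <- g$tss + window[1]
      we <- g$tss + window[2] + 1
    }
    n_ov <- sum(chip_regions$chrom == g$chrom &
                  chip_regions$start < we & chip_regions$end > max(ws, 0))
    if (n_ov == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      source = tf, target = as.character(g$id),
      edge_type = "tf_binds_gene_promoter", multiplicity = n_ov,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(source = character(), target = character(),
                      edge_type = character(), multiplicity = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' miRNA -> gene repression edges from a target table
#' @param targets data frame from [target_table()]
#' @return edge data frame with multiplicity = total site count
#' @export
mirna_to_gene_edges <- function(targets) {
  if (!nrow(targets)) {
    return(data.frame(source = character(), target = character(),
                      edge_type = character(), multiplicity = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(source = targets$mirna_id, target = targets$gene_id,
             edge_type = "mirna_represses_gene",
             multiplicity = targets$n_sites, stringsAsFactors = FALSE)
}

#' Feedback motifs through TF-regulated miRNAs
#'
#' One motif per (miRNA, focal gene) pair where the miRNA carries at least
#' one TF -> miRNA edge and targets the focal gene; focal genes are the
#' assayed factor itself, its partner components (e.g. JUN/FOS for AP-1)
#' or the upstream ligand gene. A motif is an explicit directed cycle when
#' the targeted focal gene encodes (a component of) one of the regulating
#' factors.
#'
#' @param tf_mirna_edges edge data frame from [tf_to_mirna_edges()]
#' @param targets data frame from [target_table()]
#' @param focal_genes focal gene set (default `c("IFNG","STAT1","JUN","FOS")`)
#' @param tf_gene_map named list mapping factor names to their gene-level
#'   proxies (default `list(STAT1 = "STAT1", AP1 = c("JUN", "FOS"))`)
#' @return data frame of motifs (`motif_type`, `mirna`, `target_gene`,
#'   `tfs`, `cycle`)
#' @export
find_feedback <- function(tf_mirna_edges, targets,
                          focal_genes = c("IFNG", "STAT1", "JUN", "FOS"),
                          tf_gene_map = list(STAT1 = "STAT1",
                                             AP1 = c("JUN", "FOS"))) {
  empty <- data.frame(motif_type = character(), mirna = character(),
                      target_gene = character(), tfs = character(),
                      cycle = logical(), stringsAsFactors = FALSE)
  if (!nrow(tf_mirna_edges) || !nrow(targets)) return(empty)
  rows <- list()
  for (m in sort(unique(tf_mirna_edges$target))) {
    tfs <- sort(unique(tf_mirna_edges$source[tf_mirna_edges$target == m]))
    hit <- sort(intersect(targets$gene_id[targets$mirna_id == m], focal_genes))
    for (g in hit) {
      cyc <- any(vapply(tfs, function(t) g %in% (tf_gene_map[[t]] %||% t),
                        logical(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        motif_type = "feedback", mirna = m, target_gene = g,
        tfs = paste(tfs, collapse = ","), cycle = cyc,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' (Incoherent) feed-forward motifs
#'
#' One motif per (TF, miRNA, gene) triple where the factor binds the gene's
#' promoter, the factor regulates the miRNA, and the miRNA targets the
#' gene. The attached summary reports, per factor, the number and fraction
#' of factor-bound genes also targeted by at least one factor-regulated
#' miRNA.
#'
#' @param tf_gene_edges edge data frame from [tf_to_gene_edges()]
#' @param tf_mirna_edges edge data frame from [tf_to_mirna_edges()]
#' @param targets data frame from [target_table()]
#' @return data frame of motifs (`motif_type`, `tf`, `mirna`, `gene`) with
#'   attribute `summary`
#' @export
find_feedforward <- function(tf_gene_edges, tf_mirna_edges, targets) {
  empty <- data.frame(motif_type = character(), tf = character(),
                      mirna = character(), gene = character(),
                      stringsAsFactors = FALSE)
  rows <- list()
  summ <- list()
  for (t in sort(unique(tf_gene_edges$source))) {
    bound <- sort(unique(tf_gene_edges$target[tf_gene_edges$source == t]))
    mirnas <- sort(unique(tf_mirna_edges$target[tf_mirna_edges$source == t]))
    hit_genes <- character(0)
    for (m in mirnas) {
      g_hit <- sort(intersect(targets$gene_id[targets$mirna_id == m], bound))
      hit_genes <- union(hit_genes, g_hit)
      for (g in g_hit) {
        rows[[length(rows) + 1L]] <- data.frame(
          motif_type = "feedforward", tf = t, mirna = m, gene = g,
          stringsAsFactors = FALSE)
      }
    }
    summ[[length(summ) + 1L]] <- data.frame(
      tf = t, n_bound_genes = length(bound),
      n_cotargeted = length(hit_genes),
      fraction_cotargeted = if (length(bound)) length(hit_genes) / length(bound) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  attr(out, "summary") <- if (length(summ)) do.call(rbind, summ) else
    data.frame(tf = character(), n_bound_genes = integer(),
               n_cotargeted = integer(), fraction_cotargeted = numeric())
  out
}

#' Export a regulatory network as GraphML
#'
#' Plain-text GraphML with node `kind` and edge `edge_type`/`multiplicity`
#' attributes; no graph package required to read or write it.
#'
#' @param edges combined edge data frame (`source`, `target`, `edge_type`,
#'   `multiplicity`)
#' @param path output path
#' @param node_kinds optional named character vector mapping node id to kind
#' @return `path`, invisibly
#' @export
export_graphml <- function(edges, path, node_kinds = NULL) {
  nodes <- sort(unique(c(edges$source, edges$target)))
  xml_escape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="kind" for="node" attr.name="kind" attr.type="string"/>',
    '  <key id="etype" for="edge" attr.name="edge_type" attr.type="string"/>',
    '  <key id="mult" for="edge" attr.name="multiplicity" attr.type="int"/>',
    '  <graph id="regulatory_network" edgedefault="directed">'), con)
  for (n in nodes) {
    kind <- if (!is.null(node_kinds) && n %in% names(node_kinds))
      node_kinds[[n]] else "node"
    writeLines(sprintf('    <node id="%s"><data key="kind">%s</data></node>',
                       xml_escape(n), xml_escape(kind)), con)
  }
  for (i in seq_len(nrow(edges))) {
    writeLines(sprintf(
      '    <edge source="%s" target="%s"><data key="etype">%s</data><data key="mult">%d</data></edge>',
      xml_escape(edges$source[i]), xml_escape(edges$target[i]),
      xml_escape(edges$edge_type[i]), as.integer(edges$multiplicity[i])), con)
  }
  writeLines(c("  </graph>", "</graphml>"), con)
  invisible(path)
}
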