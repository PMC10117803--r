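# Nucleotide-sugar pathway definitions and per-genome completeness calls.

#' Define a biosynthetic pathway as ordered enzyme steps
#'
#' @param name pathway name (e.g. `"UDP-d-diNAcBac"`).
#' @param steps list of steps, each a list with `role` (unique within the
#'   pathway), `queries` (reference query ids whose conservation supports
#'   the step; multiple references are combined by max, mirroring the use
#'   of the closest characterized homolog) and optional `site_spec` (id of
#'   a catalytic-site spec whose loss flag marks the step impaired).
#' @param metadata free-form list (e.g. `host_redundant` for sugars the
#'   amoeba host also makes; such pathways are called identically).
#' @return An object of class `pathway_definition`.
#' @export
pathway_definition <- function(name, steps, metadata = list()) {
  if (length(steps) < 1) stop("pathway '", name, "' has no steps")
  roles <- vapply(steps, `[[`, character(1), "role")
  if (anyDuplicated(roles)) stop("duplicate role names in '", name, "'")
  for (s in steps) {
    if (length(s$queries) < 1) {
      stop("step '", s$role, "' in '", name, "' has no reference queries")
    }
  }
  structure(list(name = name, steps = steps, metadata = metadata),
            class = "pathway_definition")
}

#' Load a pathway library from YAML
#'
#' @param path YAML with top-level `pathways`; each entry has `name`,
#'   `steps` (each with `role`, `queries`, optional `site_spec`) and any
#'   extra scalar fields, which are kept as metadata. Unknown fields
#'   inside a step are an error.
#' @return Named list of [pathway_definition()] objects.
#' @export
load_pathway_library <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pathways)) stop("config has no 'pathways' entry")
  defs <- lapply(cfg$pathways, function(p) {
    if (is.null(p$name)) stop("pathway entry without a name")
    if (is.null(p$steps)) stop("pathway '", p$name, "' has no steps")
    steps <- lapply(p$steps, function(s) {
      unknown <- setdiff(names(s), c("role", "queries", "site_spec"))
      if (length(unknown) > 0) {
        stop("unknown field(s) in a step of '", p$name, "': ",
             paste(unknown, collapse = ", "))
      }
      list(role = s$role, queries = as.character(s$queries),
           site_spec = s$site_spec)
    })
    meta <- p[setdiff(names(p), c("name", "steps"))]
    pathway_definition(p$name, steps, metadata = meta)
  })
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  defs
}

#' Path to the packaged nucleotide-sugar pathway library
#'
#' Seven pathways covering the Megavirinae nucleotide-sugar repertoire:
#' UDP-l-Rha, UDP-d-GlcNAc, UDP-d-Vio4NAc (with methylation),
#' UDP-l-Rha2NAc/Qui2NAc, UDP-d-diNAcBac, UDP-d-Qui2N/Fuc2N and
#' UDP-d-GlcA.
#'
#' @return File path under the package's `extdata`.
#' @export
pathway_library_path <- function() {
  system.file("extdata", "pathways.yaml", package = "glycoscan")
}

#' Call per-genome pathway completeness from a conservation matrix
#'
#' A step is `present` in a genome when the maximum conservation over its
#' reference queries reaches `threshold` and no attached site audit flags
#' a loss-of-function substitution; `impaired` when conservation reaches
#' the threshold but a loss is flagged; `absent` otherwise. The overall
#' call is `complete` iff all steps are present, `absent` iff all steps
#' are absent, else `partial`.
#'
#' @param matrix a `conservation_matrix` (see [build_matrix()]).
#' @param pathway a [pathway_definition()].
#' @param threshold conservation cutoff in (0, 1\]; default 0.3.
#' @param audits optional data.frame with columns `genome_id`, `site_spec`
#'   and `loss_flag` (logical) summarizing site audits per genome.
#' @return data.frame with one row per genome x step: `genome_id`,
#'   `pathway`, `step`, `role`, `conservation`, `supporting_query`,
#'   `status`, `overall`.
#' @export
call_pathway <- function(matrix, pathway, threshold = 0.3, audits = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  v <- matrix$values
  for (s in pathway$steps) {
    miss <- setdiff(s$queries, rownames(v))
    if (length(miss) > 0) {
      stop("step '", s$role, "': reference query '", miss[1],
           "' missing from matrix rows")
    }
  }
  rows <- list()
  for (g in colnames(v)) {
    statuses <- character(length(pathway$steps))
    step_rows <- list()
    for (k in seq_along(pathway$steps)) {
      s <- pathway$steps[[k]]
      cons <- v[s$queries, g]
      best <- max(cons)
      bq <- s$queries[which.max(cons)]
      lost <- FALSE
      if (!is.null(s$site_spec) && !is.null(audits)) {
        a <- audits[audits$genome_id == g & audits$site_spec == s$site_spec, ]
        lost <- nrow(a) > 0 && any(a$loss_flag)
      }
      statuses[k] <- if (best >= threshold && !lost) "present"
        else if (best >= threshold) "impaired"
        else "absent"
      step_rows[[k]] <- data.frame(
        genome_id = g, pathway = pathway$name, step = k, role = s$role,
        conservation = unname(best), supporting_query = bq,
        status = statuses[k], stringsAsFactors = FALSE)
    }
    overall <- if (all(statuses == "present")) "complete"
      else if (all(statuses == "absent")) "absent"
      else "partial"
    for (k in seq_along(step_rows)) step_rows[[k]]$overall <- overall
    rows[[g]] <- do.call(rbind, step_rows)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Summarize pathway calls to one row per genome
#'
#' @param calls result of [call_pathway()].
#' @return data.frame `genome_id`, `pathway`, `overall`, `n_present`,
#'   `n_impaired`, `n_absent`.
#' @export
summarize_pathway_calls <- function(calls) {
  agg <- lapply(split(calls, calls$genome_id), function(d) {
    data.frame(genome_id = d$genome_id[1], pathway = d$pathway[1],
               overall = d$overall[1],
               n_present = sum(d$status == "present"),
               n_impaired = sum(d$status == "impaired"),
               n_absent = sum(d$status == "absent"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, agg)
  rownames(res) <- NULL
  res
}
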