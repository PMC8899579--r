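# Boolean phenotype gating. Each rule is a conjunction of marker literals
# plus an optional disjunctive group, matching the conventional myeloid
# gates, e.g. macrophage = CD45+ CD11b+ (F4/80+ or CD68+) CD11c- Ly6G-.

#' Construct a phenotype gating rule
#'
#' @param name phenotype label
#' @param all_pos markers that must be positive
#' @param all_neg markers that must be negative
#' @param any_pos disjunctive group: at least one must be positive
#' @return a `phenotype_rule`
#' @export
phenotype_rule <- function(name, all_pos = character(), all_neg = character(),
                           any_pos = character()) {
  all_pos <- normalize_marker_names(all_pos)
  all_neg <- normalize_marker_names(all_neg)
  any_pos <- normalize_marker_names(any_pos)
  both <- intersect(c(all_pos, any_pos), all_neg)
  if (length(both))
    stop("rule '", name, "' requires marker(s) both + and -: ",
         paste(both, collapse = ", "))
  unknown <- setdiff(c(all_pos, all_neg, any_pos), panel_markers())
  if (length(unknown))
    stop("rule '", name, "' references unknown marker(s): ",
         paste(unknown, collapse = ", "))
  structure(list(name = name, all_pos = all_pos, all_neg = all_neg,
                 any_pos = any_pos), class = "phenotype_rule")
}

#' The six standard myeloid phenotype rules
#'
#' Macrophage, M1 macrophage, phagocytotic (M2) macrophage, immature
#' monocyte, dendritic cell and neutrophil, each built on the shared
#' CD45+ CD11b+ (F4/80+ or CD68+) core (neutrophils instead require
#' F4/80- CD68-). The published M1/M2 sub-gates do not repeat the base
#' macrophage exclusions (CD11c-, Ly6G-); by default they are read
#' literally, set `inherit_exclusions = TRUE` to add them.
#'
#' @param inherit_exclusions add CD11c-/Ly6G- to the M1 and M2 sub-gates
#' @return a named list of `phenotype_rule`s
#' @export
default_phenotype_rules <- function(inherit_exclusions = FALSE) {
  excl <- if (inherit_exclusions) c("CD11c", "Ly6G") else character()
  list(
    macrophage = phenotype_rule("macrophage",
      all_pos = c("CD45", "CD11b"), any_pos = c("F480", "CD68"),
      all_neg = c("CD11c", "Ly6G")),
    M1_macrophage = phenotype_rule("M1_macrophage",
      all_pos = c("CD45", "CD11b", "MHCII"), any_pos = c("F480", "CD68"),
      all_neg = excl),
    M2_macrophage = phenotype_rule("M2_macrophage",
      all_pos = c("CD45", "CD11b", "CD163", "CD206"),
      any_pos = c("F480", "CD68"), all_neg = excl),
    immature_monocyte = phenotype_rule("immature_monocyte",
      all_pos = c("CD45", "CD11b", "Ly6G"), any_pos = c("F480", "CD68"),
      all_neg = "CD11c"),
    dendritic_cell = phenotype_rule("dendritic_cell",
      all_pos = c("CD45", "CD11b", "CD11c"), any_pos = c("F480", "CD68")),
    neutrophil = phenotype_rule("neutrophil",
      all_pos = c("CD45", "CD11b", "Ly6G"), all_neg = c("F480", "CD68"))
  )
}

#' Default precedence for resolving a single primary phenotype per cell
#' @export
phenotype_precedence <- function() {
  c("neutrophil", "dendritic_cell", "M2_macrophage", "M1_macrophage",
    "immature_monocyte", "macrophage")
}

rule_satisfied <- function(cells, rule) {
  ok <- rep(TRUE, nrow(cells))
  for (m in rule$all_pos) ok <- ok & positivity(cells, m)
  for (m in rule$all_neg) ok <- ok & !positivity(cells, m)
  if (length(rule$any_pos)) {
    any_ok <- rep(FALSE, nrow(cells))
    for (m in rule$any_pos) any_ok <- any_ok | positivity(cells, m)
    ok <- ok & any_ok
  }
  ok
}

#' Assign phenotypes from gating rules
#'
#' Phenotype membership is multi-label: every rule a cell satisfies is
#' recorded in a logical `is_<phenotype>` column. The single `phenotype`
#' column carries the primary label resolved by `precedence` (first match
#' wins); cells matching no rule are `"none"`. Assignment is a pure function
#' of the positivity flags.
#'
#' @param cells a thresholded `cell_table`
#' @param rules list of `phenotype_rule`s
#' @param precedence character vector of rule names, highest priority first
#' @return the cell table with `is_*` columns and a `phenotype` column
#' @export
assign_phenotypes <- function(cells, rules = default_phenotype_rules(),
                              precedence = phenotype_precedence()) {
  stopifnot(inherits(cells, "cell_table"))
  nm <- vapply(rules, function(r) r$name, "")
  names(rules) <- nm
  sat <- vapply(rules, function(r) rule_satisfied(cells, r),
                logical(nrow(cells)))
  if (nrow(cells) == 1L) sat <- matrix(sat, nrow = 1, dimnames = list(NULL, nm))
  for (p in nm) cells[[paste0("is_", p)]] <- sat[, p]
  precedence <- c(intersect(precedence, nm), setdiff(nm, precedence))
  primary <- rep("none", nrow(cells))
  for (p in rev(precedence)) primary[sat[, p]] <- p
  cells$phenotype <- primary
  cells
}
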