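#' The scRT-mPCR gene panel
#'
#' The 13-gene multiplex panel probed in each harvested cell: the
#' glutamatergic and GABAergic markers (vGluT1; GAD65, GAD67), the glucose
#' transporters GluT1 and GluT3, hexokinase HK1, the phosphofructokinase-2
#' isoform Pfkfb3, the three phosphofructokinase-1 isoforms (muscle, liver,
#' platelet), glucose-6-phosphate dehydrogenase G6PDx, glycogen synthase
#' Gys1 and glycogen phosphorylase PygB. Amplicon sizes (first-round and
#' nested PCR, base pairs) are carried as panel metadata.
#'
#' @return A tibble with columns `gene`, `first_bp`, `nested_bp`.
#' @export
gene_panel <- function() {
  tibble(
    gene = c(
      "vGluT1", "GAD65", "GAD67", "GluT1", "GluT3", "HK1", "Pfkfb3",
      "PFK1m", "PFK1l", "PFK1p", "G6PDx", "Gys1", "PygB"
    ),
    first_bp = c(259, 375, 598, 333, 358, 472, 494, 247, 408, 306, 303, 313, 292),
    nested_bp = c(153, 248, 255, 164, 310, 330, 365, 160, 169, 219, 143, 157, 110)
  )
}

# first `k` of `n` cells positive: the joint structure across genes other
# than the GluT1/GluT3 pair is not constrained by the reported marginals, so
# detections are assigned to cell indices in this fixed, documented order.
first_k <- function(n, k) seq_len(n) <= k

#' Reference single-cell expression dataset
#'
#' Deterministically reconstructs the 59-cell detection table (31 non-Tg and
#' 28 3xTg-AD layer II/III pyramidal cells x 13-gene panel) from the reported
#' per-gene detection counts. All cells are vGluT1-positive and GAD65/GAD67
#' negative (glutamatergic phenotype). The GluT1/GluT3 joint distribution is
#' fully determined by the reported composite counts (non-Tg: 7 both, 2 only
#' GluT1, 8 only GluT3; 3xTg-AD: 1 both, 4 only GluT1, 5 only GluT3) and is
#' reproduced exactly; for every other gene only the marginal count is
#' reported, and detections are assigned to the first cells of each genotype
#' in a fixed order. Analyses that depend on the unreported joint structure
#' across those genes are therefore unsupported.
#'
#' @return A tibble with one row per cell: `cell_id`, `genotype`
#'   (`"nonTg"`/`"3xTgAD"`), and one logical column per panel gene.
#' @export
#' @examples
#' fx <- expression_fixture()
#' table(fx$genotype)
expression_fixture <- function() {
  counts <- list(
    # gene = c(k_nonTg of 31, k_3xTgAD of 28)
    HK1 = c(13, 15), Pfkfb3 = c(4, 1), PFK1m = c(26, 18),
    PFK1l = c(11, 8), PFK1p = c(18, 14), G6PDx = c(5, 5),
    Gys1 = c(0, 2), PygB = c(9, 8)
  )
  glut_joint <- list(
    # c(both, only GluT1, only GluT3)
    nonTg = c(7, 2, 8),
    `3xTgAD` = c(1, 4, 5)
  )
  build <- function(genotype, n) {
    j <- glut_joint[[genotype]]
    glut1 <- c(rep(TRUE, j[1] + j[2]), rep(FALSE, n - j[1] - j[2]))
    glut3 <- c(
      rep(TRUE, j[1]), rep(FALSE, j[2]), rep(TRUE, j[3]),
      rep(FALSE, n - sum(j))
    )
    out <- tibble(
      cell_id = sprintf("%s_%02d", genotype, seq_len(n)),
      genotype = genotype,
      vGluT1 = TRUE, GAD65 = FALSE, GAD67 = FALSE,
      GluT1 = glut1, GluT3 = glut3
    )
    for (g in names(counts)) {
      out[[g]] <- first_k(n, counts[[g]][if (genotype == "nonTg") 1 else 2])
    }
    out
  }
  bind_rows(build("nonTg", 31), build("3xTgAD", 28))
}

# Translate a feature description into an expression over panel genes.
# Accepts a gene name, boolean combinations written with AND / OR / NOT
# (e.g. "GluT1 AND GluT3"), and the pairwise shorthand "GluT1 only" /
# "only GluT1" (meaning GluT1 and not GluT3, and vice versa).
feature_expr <- function(feature, genes) {
  stopifnot(is.character(feature), length(feature) == 1)
  f <- trimws(feature)
  only <- regmatches(f, regexec("^(?:only +)?(\\w+) *(?:only)?$", f, ignore.case = TRUE))[[1]]
  if (grepl("only", f, ignore.case = TRUE) && length(only) == 2 && only[2] %in% c("GluT1", "GluT3")) {
    other <- if (only[2] == "GluT1") "GluT3" else "GluT1"
    f <- paste0(only[2], " & !", other)
  } else {
    f <- gsub("\\bAND\\b", "&", f, ignore.case = TRUE)
    f <- gsub("\\bOR\\b", "|", f, ignore.case = TRUE)
    f <- gsub("\\bNOT\\b", "!", f, ignore.case = TRUE)
  }
  expr <- str2lang(f)
  used <- all.vars(expr)
  unknown <- setdiff(used, genes)
  if (length(unknown) > 0) {
    abort(paste0("unknown gene(s) in feature: ", paste(unknown, collapse = ", ")))
  }
  expr
}

#' Occurrence of a detection feature per genotype
#'
#' Counts, in each genotype, the cells satisfying a feature: a single panel
#' gene (`"GluT1"`) or a boolean combination of two (`"GluT1 AND GluT3"`,
#' `"GluT1 OR GluT3"`, `"GluT1 only"`).
#'
#' @param records Expression records as returned by [expression_fixture()]
#'   (one row per cell, logical gene columns, `genotype` column).
#' @param feature Character feature description.
#' @return A tibble with columns `genotype`, `k`, `n`.
#' @export
#' @examples
#' occurrence(expression_fixture(), "GluT1 OR GluT3")
occurrence <- function(records, feature) {
  records <- as_tibble(records)
  if (nrow(records) == 0) abort("`records` must be non-empty")
  genes <- intersect(gene_panel()$gene, names(records))
  expr <- feature_expr(feature, genes)
  hit <- eval(expr, envir = records)
  records %>%
    mutate(.hit = hit) %>%
    group_by(.data$genotype) %>%
    summarise(k = sum(.data$.hit), n = dplyr::n(), .groups = "drop")
}

#' Genotype comparison of detection occurrences
#'
#' For each feature, tabulates detection counts in the two genotypes,
#' converts them to integer percents ([percent_occurrence()]) and tests the
#' 2x2 table with the two-sided Fisher's exact test
#' ([fisher_exact_two_sided()]).
#'
#' @param records Expression records (both genotypes must be present).
#' @param features Character vector of feature descriptions; defaults to
#'   every panel gene plus the four GluT1/GluT3 composites.
#' @return A tibble with one row per feature: `feature`, `k_nonTg`,
#'   `n_nonTg`, `pct_nonTg`, `k_3xTgAD`, `n_3xTgAD`, `pct_3xTgAD`,
#'   `p_fisher`.
#' @export
#' @examples
#' compare_genotypes(expression_fixture(), c("HK1", "GluT1 OR GluT3"))
compare_genotypes <- function(records, features = NULL) {
  records <- as_tibble(records)
  if (!all(c("nonTg", "3xTgAD") %in% records$genotype)) {
    abort("both genotypes must be present in `records`")
  }
  if (is.null(features)) {
    features <- c(
      gene_panel()$gene,
      "GluT1 AND GluT3", "GluT1 only", "GluT3 only", "GluT1 OR GluT3"
    )
  }
  purrr::map_dfr(features, function(f) {
    occ <- occurrence(records, f)
    k1 <- occ$k[occ$genotype == "nonTg"]
    n1 <- occ$n[occ$genotype == "nonTg"]
    k2 <- occ$k[occ$genotype == "3xTgAD"]
    n2 <- occ$n[occ$genotype == "3xTgAD"]
    ft <- fisher_exact_two_sided(matrix(c(k1, n1 - k1, k2, n2 - k2), 2, 2,
      byrow = TRUE
    ))
    tibble(
      feature = f,
      k_nonTg = k1, n_nonTg = n1, pct_nonTg = percent_occurrence(k1, n1),
      k_3xTgAD = k2, n_3xTgAD = n2, pct_3xTgAD = percent_occurrence(k2, n2),
      p_fisher = ft$p
    )
  })
}

#' Write / read expression records as CSV
#'
#' One row per cell, a `genotype` column, and one logical column per panel
#' gene, with header names exactly the panel gene names.
#'
#' @param records Expression records tibble.
#' @param path CSV file path.
#' @return `read_expression_records()` returns a tibble with logical gene
#'   columns.
#' @export
write_expression_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_records
#' @export
read_expression_records <- function(path) {
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  for (g in intersect(gene_panel()$gene, names(df))) df[[g]] <- as.logical(df[[g]])
  df
}
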