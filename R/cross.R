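#' Mendelian cross specification with lethality and rescue rules
#'
#' Describes a fly cross chromosome by chromosome: each parent carries an
#' allele pair per chromosome and contributes one allele with equal
#' probability (no recombination within chromosomes — balancers suppress it —
#' and free assortment between chromosomes). Lethal rules are allele-count
#' predicates over the zygote genotype, optionally waived by rescue alleles;
#' a typical set encodes balancer homozygote lethality (e.g. `TM6B: 2`) and
#' mutant-over-deficiency lethality unless a rescue transgene is present.
#'
#' @param chromosomes named list; each element is
#'   `list(mother = c(a1, a2), father = c(b1, b2))` of allele labels.
#' @param lethal_rules list of rules; each rule is
#'   `list(requires = c(allele = count, ...), unless = c(alleles))` — the
#'   genotype is lethal when it carries at least `count` copies of every
#'   `requires` allele and none of the `unless` alleles.
#' @return An object of class `cross_spec`.
#' @export
cross_spec <- function(chromosomes, lethal_rules = list()) {
  for (nm in names(chromosomes)) {
    ch <- chromosomes[[nm]]
    if (!all(c("mother", "father") %in% names(ch)) ||
        length(ch$mother) != 2 || length(ch$father) != 2)
      stop("cross_spec: each chromosome needs mother/father allele pairs",
           call. = FALSE)
  }
  declared <- unique(unlist(lapply(chromosomes, unlist)))
  for (r in lethal_rules) {
    used <- c(names(r$requires), r$unless)
    bad <- setdiff(used, declared)
    if (length(bad))
      stop("cross_spec: rule references undeclared allele(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(chromosomes = chromosomes, lethal_rules = lethal_rules),
            class = "cross_spec")
}

genotype_is_lethal <- function(allele_counts, rules) {
  for (r in rules) {
    req <- r$requires
    hit <- all(vapply(names(req), function(a)
      sum(allele_counts[names(allele_counts) == a]) >= req[[a]], logical(1)))
    if (hit && !is.null(r$unless) &&
        any(vapply(r$unless, function(a)
          sum(allele_counts[names(allele_counts) == a]) >= 1, logical(1))))
      hit <- FALSE
    if (hit) return(TRUE)
  }
  FALSE
}

#' Expected progeny-class distribution
#'
#' Enumerates every gamete combination with equal segregation, applies the
#' lethal rules (with rescue exemptions) and renormalizes over survivors.
#' Genotype classes are labeled per chromosome as `allele1/allele2` (alleles
#' sorted within a chromosome) joined by `"; "`.
#'
#' @param cross a [cross_spec].
#' @param class_of optional function mapping a genotype (named list of
#'   chromosome allele pairs) to a class label; defaults to the full genotype
#'   string, so classes can be pooled afterwards.
#' @return An object of class `progeny_distribution`: data.frame `classes`
#'   with columns `class`, `raw_freq` (pre-selection conception frequency),
#'   `percent` (among viable adults; lethal classes report 0), plus
#'   `viable_mass` (fraction of conceptions surviving).
#' @export
expected_progeny <- function(cross, class_of = NULL) {
  chroms <- cross$chromosomes
  nms <- names(chroms)
  # all gamete combinations: 4 per chromosome (2 maternal x 2 paternal)
  per_chrom <- lapply(chroms, function(ch)
    expand.grid(m = ch$mother, f = ch$father, stringsAsFactors = FALSE))
  idx <- expand.grid(lapply(per_chrom, function(g) seq_len(nrow(g))))
  n_combo <- nrow(idx)
  label <- character(n_combo)
  lethal <- logical(n_combo)
  for (k in seq_len(n_combo)) {
    geno <- lapply(seq_along(nms), function(j) {
      g <- per_chrom[[j]][idx[k, j], ]
      c(g$m, g$f)
    })
    names(geno) <- nms
    counts <- table(unlist(geno))
    counts <- stats::setNames(as.integer(counts), names(counts))
    lethal[k] <- genotype_is_lethal(counts, cross$lethal_rules)
    label[k] <- if (is.null(class_of)) {
      paste(vapply(geno, function(a) paste(sort(a), collapse = "/"),
                   character(1)), collapse = "; ")
    } else class_of(geno)
  }
  raw <- tapply(rep(1 / n_combo, n_combo), label, sum)
  surv <- tapply(ifelse(lethal, 0, 1 / n_combo), label, sum)
  viable_mass <- sum(surv)
  if (viable_mass == 0)
    stop("expected_progeny: all progeny classes are lethal", call. = FALSE)
  classes <- data.frame(class = names(raw),
                        raw_freq = as.numeric(raw),
                        percent = 100 * as.numeric(surv) / viable_mass,
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(classes = classes, viable_mass = viable_mass),
            class = "progeny_distribution")
}

#' @export
print.progeny_distribution <- function(x, ...) {
  cat(sprintf("<progeny_distribution> viable mass %.3f\n", x$viable_mass))
  df <- x$classes
  df$percent <- round(df$percent, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Observed progeny percentages from class counts
#'
#' @param class_counts named (or bare) numeric vector of per-class adult
#'   counts.
#' @param total total number of progeny scored; must be >= sum of counts
#'   and > 0.
#' @return data.frame with `class`, `count`, `percent` (exact) and
#'   `percent_rounded` (one decimal, as reported).
#' @export
observed_percentages <- function(class_counts, total) {
  if (total <= 0) stop("observed_percentages: total must be > 0", call. = FALSE)
  if (sum(class_counts) > total)
    stop("observed_percentages: counts exceed total", call. = FALSE)
  nm <- names(class_counts)
  if (is.null(nm)) nm <- paste0("class", seq_along(class_counts))
  pct <- 100 * as.numeric(class_counts) / total
  data.frame(class = nm, count = as.numeric(class_counts),
             percent = pct, percent_rounded = round(pct, 1),
             stringsAsFactors = FALSE)
}

#' The packaged rescue-cross specification
#'
#' The cross used to test rescue of deficiency lethality by neuronal
#' re-expression: mothers `mutant/TM6B` (carrying the X-linked pan-neuronal
#' driver, so every progeny inherits it) crossed to fathers
#' `UAS-rescue/CyO; Df/TM6B`. Third-chromosome combinations segregate
#' 1:1:1:1; the second chromosome contributes the UAS rescue transgene or the
#' CyO balancer 1:1. `TM6B/TM6B` zygotes die (balancer homozygote), and
#' `mutant/Df` zygotes die unless they carry the UAS transgene.
#'
#' @return A [cross_spec] for use with [expected_progeny()] together with
#'   [rescue_cross_classes()].
#' @export
rescue_cross_spec <- function() {
  cross_spec(
    chromosomes = list(
      chr2 = list(mother = c("+", "+"), father = c("UAS", "CyO")),
      chr3 = list(mother = c("MI107", "TM6B"), father = c("Df", "TM6B"))
    ),
    lethal_rules = list(
      list(requires = c(TM6B = 2)),
      list(requires = c(MI107 = 1, Df = 1), unless = "UAS")
    )
  )
}

#' Class labeling for the packaged rescue cross
#'
#' Pools raw genotypes into the four reported progeny classes:
#' heterozygous deficiency (mutant or Df over balancer) with or without the
#' rescue transgene, and homozygous deficiency (mutant over Df) with or
#' without it.
#'
#' @return A labeling function for [expected_progeny()]'s `class_of`.
#' @export
rescue_cross_classes <- function() {
  function(geno) {
    homo <- all(c("MI107", "Df") %in% geno$chr3)
    uas <- "UAS" %in% geno$chr2
    if (all(geno$chr3 == "TM6B")) return("balancer homozygote")
    paste(if (homo) "homozygous deficiency" else "heterozygous deficiency",
          if (uas) "with rescue" else "without rescue")
  }
}
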