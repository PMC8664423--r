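# Phenotype derivations and the family-controlled group comparison.

#' Fulton's condition factor
#'
#' `K = 100 * weight_g / length_cm^3`, with length supplied in millimetres.
#' A fish of 10 g at 100 mm has K = 1 exactly.
#'
#' @param weight_g body weight in grams (> 0).
#' @param length_mm fork length in millimetres (> 0).
#' @return unitless condition factor, vectorized.
#' @export
condition_factor <- function(weight_g, length_mm) {
  if (any(weight_g <= 0) || any(length_mm <= 0))
    stop("weight and length must be positive")
  100 * weight_g / (length_mm / 10)^3
}

#' Family-controlled group comparison (family-means ANOVA)
#'
#' Controls among-family variance by averaging the trait within each
#' family and running a one-way ANOVA of family means between groups.
#' With F families total this yields F-statistic degrees of freedom
#' (1, F - 2).
#'
#' @param records data.frame with columns family, group, and the trait.
#' @param trait name of the trait column.
#' @return list with f_stat, df1, df2, p, and the family means table.
#' @export
family_anova <- function(records, trait) {
  if (!trait %in% names(records)) stop("unknown trait: ", trait)
  fam_group <- unique(records[, c("family", "group")])
  if (anyDuplicated(fam_group$family))
    stop("a family spans both groups")
  fm <- aggregate(records[[trait]],
                  by = list(family = records$family, group = records$group),
                  FUN = mean)
  names(fm)[3] <- "mean_trait"
  if (any(table(fm$group) < 2)) stop("need >= 2 families per group")
  fit <- lm(mean_trait ~ group, data = fm)
  av <- suppressWarnings(anova(fit))
  ssb <- av[["Sum Sq"]][1]; sse <- av[["Sum Sq"]][2]
  f <- av[["F value"]][1]; p <- av[["Pr(>F)"]][1]
  tot <- sum((fm$mean_trait - mean(fm$mean_trait))^2)
  scale2 <- sum(fm$mean_trait^2) + .Machine$double.xmin
  if (!is.finite(f) || tot <= 1e-12 * scale2 || ssb <= 1e-12 * tot) {
    # degenerate case: no between-group variance in the family means
    f <- 0; p <- 1
  }
  list(f_stat = f,
       df1 = av[["Df"]][1], df2 = av[["Df"]][2],
       p = p,
       family_means = fm)
}

#' Phenotype summary by group
#'
#' @param records data.frame with group and numeric trait columns.
#' @param traits character vector of trait column names.
#' @return data.frame of per-group mean and SD per trait.
#' @export
phenotype_summary <- function(records,
                              traits = c("length_mm", "weight_g",
                                         "condition_k")) {
  traits <- intersect(traits, names(records))
  do.call(rbind, lapply(traits, function(tr) {
    ag <- aggregate(records[[tr]], by = list(group = records$group),
                    FUN = function(x) c(mean = mean(x), sd = sd(x)))
    data.frame(trait = tr, group = ag$group,
               mean = ag$x[, "mean"], sd = ag$x[, "sd"])
  }))
}
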