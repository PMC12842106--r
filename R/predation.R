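#' Container-level predation table
#'
#' One row per container with the site it was placed at, the phenotype of
#' the beetle it held, and the binary attack outcome.
#'
#' @param site character/factor of sites.
#' @param phenotype character/factor of phenotype colors.
#' @param attacked integer 0/1 outcomes.
#' @param container_id optional ids (generated when absent).
#' @return A data.frame of class \code{predation_table}.
#' @export
predation_table <- function(site, phenotype, attacked, container_id = NULL) {
  if (!all(attacked %in% c(0, 1)))
    stop("attacked must be 0/1")
  n <- length(attacked)
  if (is.null(container_id)) container_id <- sprintf("C%03d", seq_len(n))
  out <- data.frame(container_id = container_id,
                    site = factor(site), phenotype = factor(phenotype),
                    attacked = as.integer(attacked))
  class(out) <- c("predation_table", "data.frame")
  out
}

#' Read a predation experiment CSV
#'
#' Expects columns \code{container_id, site, phenotype, attacked}
#' (\code{attacked} in \{0,1\}).
#'
#' @param path CSV path.
#' @return A \code{predation_table}. A message reports the design; a
#'   single-site or single-phenotype file loads but is flagged because the
#'   full site-by-color model is then unavailable.
#' @export
read_predation_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("empty predation table: ", path)
  need <- c("site", "phenotype", "attacked")
  if (!all(need %in% names(tab)))
    stop("predation CSV needs columns site, phenotype, attacked")
  if (!all(tab$attacked %in% c(0, 1)))
    stop("attacked must be 0 or 1; found: ",
         paste(utils::head(setdiff(unique(tab$attacked), c(0, 1))),
               collapse = ", "))
  out <- predation_table(tab$site, tab$phenotype, tab$attacked,
                         if ("container_id" %in% names(tab))
                           tab$container_id else NULL)
  if (nlevels(out$site) < 2 || nlevels(out$phenotype) < 2)
    message("fewer than 2 sites or phenotypes: full site x color model ",
            "unavailable")
  message(nrow(out), " containers; ", nlevels(out$site), " site(s) x ",
          nlevels(out$phenotype), " phenotype(s)")
  out
}

#' Fit a binomial logit GLM to container attacks
#'
#' Bernoulli (container-level) logistic regression fit by iteratively
#' reweighted least squares to tolerance 1e-8. Perfect separation (fitted
#' probabilities at the 0/1 boundary) is flagged; the deviance is still
#' reported.
#'
#' @param table a \code{predation_table}.
#' @param formula model formula over \code{site}, \code{phenotype} and
#'   their interaction (default the saturated \code{site * phenotype}).
#' @return The fitted \code{glm} with an extra logical attribute
#'   \code{separation}.
#' @export
fit_binomial_glm <- function(table,
                             formula = attacked ~ site * phenotype) {
  fit <- suppressWarnings(
    stats::glm(formula, family = stats::binomial("logit"), data = table,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  eta <- abs(fit$linear.predictors)
  attr(fit, "separation") <- any(eta > 15) || !fit$converged
  fit
}

#' Analysis of deviance for the predation experiment
#'
#' Type-II likelihood-ratio chi-square tests: each main effect is tested
#' against the model containing the other main effect, and the
#' site-by-color interaction is tested as additive versus saturated. On a
#' 2x2 design every test has one degree of freedom.
#'
#' @param table a \code{predation_table} with both factors at >= 2 levels.
#' @return A data.frame of class \code{deviance_table} with columns
#'   \code{term, chisq, df, p}; terms that a degenerate design cannot
#'   support are omitted.
#' @export
deviance_tests <- function(table) {
  has_site <- nlevels(droplevels(table$site)) >= 2
  has_col <- nlevels(droplevels(table$phenotype)) >= 2
  rows <- list()
  lrt <- function(reduced, full, term) {
    chisq <- stats::deviance(reduced) - stats::deviance(full)
    df <- full$rank - reduced$rank
    data.frame(term = term, chisq = chisq, df = df,
               p = stats::pchisq(chisq, df, lower.tail = FALSE))
  }
  if (has_site && has_col) {
    m_add <- fit_binomial_glm(table, attacked ~ site + phenotype)
    m_site <- fit_binomial_glm(table, attacked ~ phenotype)
    m_col <- fit_binomial_glm(table, attacked ~ site)
    m_full <- fit_binomial_glm(table, attacked ~ site * phenotype)
    rows$site <- lrt(m_site, m_add, "site")
    rows$color <- lrt(m_col, m_add, "color")
    rows$interaction <- lrt(m_add, m_full, "site:color")
  } else if (has_site) {
    rows$site <- lrt(fit_binomial_glm(table, attacked ~ 1),
                     fit_binomial_glm(table, attacked ~ site), "site")
  } else if (has_col) {
    rows$color <- lrt(fit_binomial_glm(table, attacked ~ 1),
                      fit_binomial_glm(table, attacked ~ phenotype),
                      "color")
  } else stop("degenerate design: no factor with 2 levels")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("deviance_table", "data.frame")
  out
}

#' Cell and marginal attack proportions
#'
#' @param table a \code{predation_table}.
#' @return list with \code{cells} (data.frame site, phenotype, n, attacks,
#'   proportion), \code{site_margin}, \code{phenotype_margin},
#'   \code{grand_mean}.
#' @export
attack_summary <- function(table) {
  stopifnot(nrow(table) > 0)
  agg <- stats::aggregate(attacked ~ site + phenotype, table,
                          function(x) c(n = length(x), a = sum(x)))
  cells <- data.frame(site = agg$site, phenotype = agg$phenotype,
                      n = agg$attacked[, "n"],
                      attacks = agg$attacked[, "a"])
  cells$proportion <- cells$attacks / cells$n
  margin <- function(f) {
    m <- tapply(table$attacked, f, mean)
    data.frame(level = names(m), proportion = as.numeric(m))
  }
  list(cells = cells,
       site_margin = margin(table$site),
       phenotype_margin = margin(table$phenotype),
       grand_mean = mean(table$attacked))
}
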