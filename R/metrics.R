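#' Steps required to reach consistently positive MoS
#'
#' The individual-level recovery metric: the index of the first recovery
#' step of the terminal run of non-negative MoS values. "Consistently"
#' means all later recovery steps are also non-negative, so an isolated
#' positive step followed by a negative one does not count. By convention
#' at least one recovery step is always required (minimum return value 1).
#' If the final analysed step is still negative the count is undetermined
#' and `K + 1` is returned with attribute `undetermined = TRUE`.
#'
#' @param mos_post Numeric vector of recovery-step MoS values (m), in step
#'   order (Post1, Post2, ...).
#' @return Integer count, with attribute `undetermined` (logical).
#' @export
#' @examples
#' steps_to_positive(c(-0.10, -0.05, 0.02, 0.04, 0.06, 0.07, 0.07, 0.07)) # 3
steps_to_positive <- function(mos_post) {
  if (length(mos_post) == 0) stop("no post-perturbation steps supplied")
  if (anyNA(mos_post)) stop("mos_post contains missing values")
  neg <- which(mos_post < 0)
  if (length(neg) == 0) {
    k <- 1L
    undet <- FALSE
  } else if (neg[length(neg)] == length(mos_post)) {
    k <- length(mos_post) + 1L
    undet <- TRUE
  } else {
    k <- neg[length(neg)] + 1L
    undet <- FALSE
  }
  structure(k, undetermined = undet)
}

#' Per-perturbation recovery metrics
#'
#' Reduces labelled step records to one row per perturbation: the number of
#' steps to consistently positive MoS, the per-step MoS deficits relative
#' to the pre-perturbation baseline (Post-k minus Base), and bookkeeping.
#'
#' @param labelled_steps A `step_records` data.frame from [label_steps()]
#'   (must carry the `"base"` attribute).
#' @param n_post Number of recovery steps analysed (default 8).
#' @return A `recovery_metrics` data.frame: `pert_id`, `limb` (of Post1),
#'   `base_mos`, `n_post`, `steps_to_positive`, `undetermined`, and deficit
#'   columns `deficit_post1` ... `deficit_post<n_post>` (m).
#' @export
recovery_metrics <- function(labelled_steps, n_post = 8) {
  base_tab <- attr(labelled_steps, "base")
  if (is.null(base_tab))
    stop("labelled_steps must come from label_steps() (missing base attribute)")
  out <- lapply(base_tab$pert_id, function(id) {
    sel <- !is.na(labelled_steps$pert_id) & labelled_steps$pert_id == id
    post_lab <- paste0("Post", seq_len(n_post))
    post <- labelled_steps[sel & labelled_steps$label %in% post_lab, ,
                           drop = FALSE]
    post <- post[order(post$touchdown_time), , drop = FALSE]
    if (nrow(post) == 0) return(NULL)
    base_mos <- base_tab$base_mos[base_tab$pert_id == id]
    stp <- steps_to_positive(post$mos)
    defs <- setNames(rep(NA_real_, n_post), paste0("deficit_post", seq_len(n_post)))
    defs[match(post$label, post_lab)] <- post$mos - base_mos
    cbind(data.frame(pert_id = id, limb = post$limb[1], base_mos = base_mos,
                     n_post = nrow(post), steps_to_positive = as.integer(stp),
                     undetermined = attr(stp, "undetermined"),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(defs)))
  })
  out <- do.call(rbind, out)
  class(out) <- c("recovery_metrics", "data.frame")
  out
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf("<recovery_metrics> %d perturbations; steps to positive MoS: %s\n",
              nrow(x), paste(x$steps_to_positive, collapse = " ")))
  print.data.frame(as.data.frame(x)[, 1:6])
  invisible(x)
}

#' Group-level steps to return to baseline MoS
#'
#' The group-level recovery metric: how many recovery steps differ
#' significantly from the pre-perturbation baseline. Each recovery step is
#' compared with Base across subjects (paired comparisons with the chosen
#' multiple-comparison adjustment over the family of recovery steps), and
#' the count is the length of the initial run of significant steps: the
#' largest m such that Post1..Postm are all significant and Post(m+1) is
#' not; 0 if Post1 is not significant. Patterns with interior
#' non-significant steps are reduced by the same initial-run rule (flagged
#' in the attribute `pattern`).
#'
#' @param group_data data.frame with columns `subject`, `step` (one of
#'   `"Base"`, `"Post1"`, ..., in a complete balanced design) and `mos`.
#' @param alpha Familywise significance level (default 0.05).
#' @param adjustment `"bonferroni"` (default, matching the group analyses
#'   this metric reduces) or `"none"`.
#' @return Integer count with attributes `p_adjusted` (named vector) and
#'   `pattern` (logical significance per step).
#' @export
steps_to_baseline <- function(group_data, alpha = 0.05,
                              adjustment = c("bonferroni", "none")) {
  adjustment <- match.arg(adjustment)
  need <- c("subject", "step", "mos")
  group_data <- .check_table(group_data, need, "group_data")
  steps <- unique(group_data$step)
  post_steps <- steps[grepl("^Post[0-9]+$", steps)]
  post_steps <- post_steps[order(as.integer(sub("Post", "", post_steps)))]
  if (!"Base" %in% steps || length(post_steps) == 0)
    stop("group_data must contain a Base level and Post1..K levels")
  tab <- table(group_data$subject, group_data$step)
  if (any(tab != 1))
    stop("unbalanced design: every subject needs exactly one value per step")
  subjects <- rownames(tab)
  get_col <- function(stp) {
    x <- group_data$mos[group_data$step == stp]
    names(x) <- group_data$subject[group_data$step == stp]
    x[subjects]
  }
  base <- get_col("Base")
  p <- vapply(post_steps, function(stp) {
    d <- get_col(stp) - base
    if (sd(d) == 0) return(if (all(d == 0)) 1 else 0)
    2 * pt(-abs(mean(d) / (sd(d) / sqrt(length(d)))), df = length(d) - 1)
  }, numeric(1))
  p_adj <- if (adjustment == "bonferroni") pmin(1, p * length(p)) else p
  sig <- p_adj < alpha
  m <- if (!sig[1]) 0L else {
    runlen <- which(!sig)
    if (length(runlen) == 0) length(sig) else runlen[1] - 1L
  }
  structure(as.integer(m), p_adjusted = p_adj, pattern = sig)
}
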