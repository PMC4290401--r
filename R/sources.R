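# Attribution of total dietary sodium to the nine FNDDS food groups.

#' Food-group contributions to dietary sodium
#'
#' Per reporting domain, the survey-weighted total of recall-day sodium in
#' each FNDDS group divided by the weighted grand total, as a percentage.
#' Contributions are computed on observed recall-day sodium (a ratio of
#' weighted totals), not on modeled usual intake.
#'
#' @param recalls validated recall table
#' @param map validated food-group map (see [validate_foodgroups()])
#' @param demo demographics with weights and the `by` columns
#' @param by domain columns; NULL for one overall domain
#' @param lenient if TRUE, unmapped food codes are assigned to a tenth
#'   "Unmapped" bucket instead of raising an error
#' @return data.frame: domain columns, group_id, group_name,
#'   percent_of_total_sodium (per domain these sum to 100)
#' @export
group_contributions <- function(recalls, map, demo, by = NULL,
                                lenient = FALSE) {
  assert_columns(demo, c("person_id", "weight"), "demographics")
  if (!is.null(by)) assert_columns(demo, by, "demographics")
  gid <- map$group_id[match(recalls$food_code, map$food_code)]
  if (anyNA(gid)) {
    codes <- unique(recalls$food_code[is.na(gid)])
    if (!lenient)
      fail("saltshift_domain_error",
           "group_contributions: unmapped food code(s): %s%s",
           paste(utils::head(codes, 10), collapse = ", "),
           if (length(codes) > 10) sprintf(" (+%d more)", length(codes) - 10) else "")
    gid[is.na(gid)] <- 10L
  }
  dat <- data.frame(person_id = recalls$person_id, group_id = gid,
                    sodium_mg = recalls$sodium_mg)
  dat <- merge(dat, demo[, unique(c("person_id", "weight", by))],
               by = "person_id")
  dom <- if (is.null(by)) factor(rep("(all)", nrow(dat))) else {
    interaction(dat[by], drop = TRUE, sep = "|")
  }
  groups <- rbind(fndds_groups(),
                  data.frame(group_id = 10L, group_name = "Unmapped"))
  rows <- lapply(levels(dom), function(d) {
    idx <- dom == d
    ws <- tapply(dat$weight[idx] * dat$sodium_mg[idx],
                 factor(dat$group_id[idx], levels = groups$group_id), sum)
    ws[is.na(ws)] <- 0
    present <- if (any(dat$group_id[idx] == 10L)) 1:10 else 1:9
    pct <- 100 * ws[present] / sum(ws)
    out <- data.frame(group_id = groups$group_id[present],
                      group_name = groups$group_name[present],
                      percent_of_total_sodium = as.vector(pct),
                      stringsAsFactors = FALSE)
    if (!is.null(by)) {
      doms <- strsplit(d, "|", fixed = TRUE)[[1]]
      for (i in seq_along(by)) out[[by[i]]] <- doms[i]
      out <- out[c(by, setdiff(names(out), by))]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
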