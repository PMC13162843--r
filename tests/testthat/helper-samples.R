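# Builders for small in-memory repertoire fixtures.

make_sample <- function(templates,
                        ids = sprintf("CLONE%03d", seq_along(templates)),
                        status = rep("productive", length(templates)),
                        sample_id = "s1", subject_id = "p1",
                        compartment = "blood", timepoint_days = -7L,
                        frequencies = FALSE) {
  x <- tibble::tibble(
    sample_id = sample_id,
    subject_id = subject_id,
    compartment = compartment,
    timepoint_days = as.integer(timepoint_days),
    rearrangement = ids,
    cdr3_aa = paste0("CASS", seq_along(templates)),
    v_gene = "TCRBV05-01",
    j_gene = "TCRBJ02-01",
    status = status,
    templates = as.integer(templates)
  )
  if (frequencies) x <- compute_frequencies(filter_productive(x))
  x
}

# A clone-pair row with frequencies kept exactly consistent with
# templates/total ratios.
make_pair <- function(baseline_templates, followup_templates,
                      baseline_total = 2e5, followup_total = 2e5,
                      ids = sprintf("CLONE%03d",
                        seq_along(baseline_templates))) {
  tibble::tibble(
    rearrangement = ids,
    baseline_templates = as.integer(baseline_templates),
    baseline_freq = baseline_templates / baseline_total,
    followup_templates = as.integer(followup_templates),
    followup_freq = followup_templates / followup_total,
    baseline_total = baseline_total,
    followup_total = followup_total
  )
}

# Write a clonotype TSV in the immunoseq dialect from raw row vectors,
# bypassing the package writer (so reader tests do not depend on it).
write_immunoseq_fixture <- function(path, rearrangement, templates,
                                    status = rep("In", length(templates)),
                                    amino = rep("CASSL", length(templates))) {
  df <- data.frame(
    rearrangement = rearrangement,
    aminoAcid = amino,
    `count (templates/estimate)` = templates,
    sequenceStatus = status,
    vGeneName = "TCRBV05-01",
    jGeneName = "TCRBJ02-01",
    check.names = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of the
# C(n, n_a) equally likely rank allocations (no ties assumed).
wilcox_enum_p <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  alloc <- utils::combn(length(pooled), n_a)
  u_all <- apply(alloc, 2, function(idx) sum(seq_along(pooled)[idx])) -
    n_a * (n_a + 1) / 2
  # ranks of a under H0 are a uniform random subset; compare via the
  # rank-sum statistic
  total <- ncol(alloc)
  min(1, 2 * min(sum(u_all <= u_obs), sum(u_all >= u_obs)) / total)
}
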