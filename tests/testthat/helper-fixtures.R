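# shared fixtures: all data are built in code at test time

rot_about <- radius3d:::rotation_about

rand_rot <- function() {
  rot_about(c(1, 0, 0), runif(1, 0, 360)) %*%
    rot_about(c(0, 1, 0), runif(1, 0, 360)) %*%
    rot_about(c(0, 0, 1), runif(1, 0, 360))
}

# unsigned angle between two lines (directions up to sign), radians
line_angle <- function(u, v) acos(min(1, abs(sum(u * v))))

blob_cloud <- function(n = 300, sd = 15) matrix(rnorm(n * 3, sd = sd), ncol = 3)

cohort_landmark_table <- function(cohort) {
  do.call(rbind, lapply(cohort$patients, function(p)
    cbind(patient_id = p$patient_id, p$landmarks, side = p$side)))
}

cohort_xray_table <- function(cohort) {
  do.call(rbind, lapply(cohort$patients, function(p)
    do.call(rbind, lapply(names(p$xray), function(st) {
      x <- p$xray[[st]]
      data.frame(patient_id = p$patient_id, stage = st,
                 landmark = names(x),
                 u = vapply(x, `[`, numeric(1), 1),
                 v = vapply(x, `[`, numeric(1), 2))
    }))))
}

# default anatomic triad used across indices/synthetic tests
default_triad <- function() {
  m <- cohort_spec()$postop_triad_means
  reference_triad(m[1, ], m[2, ], m[3, ])
}
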