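#' Default arm muscle set with signed moment arms
#'
#' Twelve muscles spanning the shoulder, elbow, and wrist
#' flexion--extension axes: anterior/posterior deltoid (AD, PD),
#' pectoralis major (Pec), teres major (TM), biceps long/short heads
#' (BicL, BicS), triceps long/lateral heads (TriLo, TriLa),
#' brachioradialis (Br), and the wrist muscles FCR, FCU, ECR.
#' Each entry is a constant signed lever arm about one joint: positive
#' for flexors (the muscle shortens as the joint flexes), negative for
#' extensors. BicL and TriLo are biarticular (shoulder + elbow); all
#' other muscles act about a single joint.
#'
#' The magnitudes (1--4 cm) are representative of adult upper-limb
#' anatomy; they set the scale of the length excursions, not anatomical
#' detail. A first-order (constant moment arm) length model is all the
#' downstream analyses require.
#'
#' @return A tibble with columns `muscle`, `joint`
#'   (`"shoulder"|"elbow"|"wrist"`), and `moment_arm_m` (signed, metres).
#' @seealso [muscle_base_lengths()], [antagonist_pairs()],
#'   [muscle_lengths_from_angles()]
#' @export
#' @examples
#' moment_arms()
moment_arms <- function() {
  tibble::tribble(
    ~muscle, ~joint,     ~moment_arm_m,
    "AD",    "shoulder",  0.030,
    "PD",    "shoulder", -0.030,
    "Pec",   "shoulder",  0.040,
    "TM",    "shoulder", -0.035,
    "BicL",  "shoulder",  0.015,
    "BicL",  "elbow",     0.035,
    "TriLo", "shoulder", -0.015,
    "TriLo", "elbow",    -0.030,
    "BicS",  "elbow",     0.032,
    "TriLa", "elbow",    -0.028,
    "Br",    "elbow",     0.025,
    "FCR",   "wrist",     0.015,
    "FCU",   "wrist",     0.018,
    "ECR",   "wrist",    -0.016
  )
}

#' Muscle lengths at the reference posture
#'
#' Reference (all joint angles zero) musculotendon lengths for the
#' default muscle set, 25--35 cm depending on the muscle.
#'
#' @return A tibble with columns `muscle` and `base_length_m`.
#' @export
muscle_base_lengths <- function() {
  tibble::tribble(
    ~muscle, ~base_length_m,
    "AD",    0.28,
    "PD",    0.28,
    "Pec",   0.32,
    "TM",    0.30,
    "BicL",  0.35,
    "TriLo", 0.35,
    "BicS",  0.32,
    "TriLa", 0.30,
    "Br",    0.27,
    "FCR",   0.28,
    "FCU",   0.28,
    "ECR",   0.29
  )
}

#' Antagonist muscle pairs used for co-contraction
#'
#' The seven flexor--extensor pairings over which wasted contraction is
#' computed: AD-PD, Pec-TM, BicL-TriLo, BicS-TriLa, Br-TriLa, FCR-ECR,
#' and FCU-ECR. TriLa and ECR each appear in two pairs.
#'
#' @return A tibble with columns `pair`, `flexor`, and `extensor`.
#' @export
#' @examples
#' antagonist_pairs()
antagonist_pairs <- function() {
  tibble::tribble(
    ~pair,         ~flexor, ~extensor,
    "AD-PD",       "AD",    "PD",
    "Pec-TM",      "Pec",   "TM",
    "BicL-TriLo",  "BicL",  "TriLo",
    "BicS-TriLa",  "BicS",  "TriLa",
    "Br-TriLa",    "Br",    "TriLa",
    "FCR-ECR",     "FCR",   "ECR",
    "FCU-ECR",     "FCU",   "ECR"
  )
}

# Validate a user-supplied moment-arm table against the invariants the
# generator relies on. Returns the table invisibly.
check_moment_arms <- function(arms, base_lengths) {
  needed <- c("muscle", "joint", "moment_arm_m")
  if (!all(needed %in% names(arms))) {
    abort("Moment-arm table needs columns muscle, joint, moment_arm_m.")
  }
  if (!all(c("muscle", "base_length_m") %in% names(base_lengths))) {
    abort("Base-length table needs columns muscle, base_length_m.")
  }
  per_muscle <- tapply(arms$moment_arm_m != 0, arms$muscle, any)
  if (!all(per_muscle)) {
    abort("Every muscle must have at least one nonzero moment arm.")
  }
  missing <- setdiff(unique(arms$muscle), base_lengths$muscle)
  if (length(missing)) {
    abort(paste0("No base length for muscle(s): ", paste(missing, collapse = ", ")))
  }
  invisible(arms)
}
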