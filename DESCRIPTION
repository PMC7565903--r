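Package: ipmnbalance
Title: Risk-Benefit Balance Analysis for IPMN Surgical Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for risk-benefit analysis of surgical decisions in branch-duct
    and mixed-type intraductal papillary mucinous neoplasm (IPMN). Scores each
    patient's malignancy probability with a logistic nomogram surrogate and their
    surgical risk with a serious-complication surrogate, builds the
    false-negative versus complication-weighted false-positive balance worksheet
    over a cutoff grid, selects the cutoff where missed malignancies equal
    complication-weighted unnecessary surgeries, evaluates cutoffs with
    confusion-matrix statistics, ROC/AUC (DeLong confidence intervals) and
    Hosmer-Lemeshow calibration, and applies the direct per-patient
    probability-versus-risk decision rule. Includes a synthetic-cohort generator
    emulating a pancreatectomy cohort with graded Clavien-Dindo complications so
    the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
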