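Package: dravetpbpk
Title: Whole-Body PBPK Models of Clobazam, N-Desmethylclobazam and
    Stiripentol Co-Therapy in Dravet Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Physiologically based pharmacokinetic (PBPK) simulation of
    clobazam (CLB), its active metabolite N-desmethylclobazam (N-CLB) and
    stiripentol (STP) in adults and pediatric Dravet syndrome patients.
    Implements Rodgers-Rowland tissue partitioning, well-stirred liver
    back-calculation of intrinsic clearance, dynamic competitive
    CYP-inhibition drug-drug interactions stratified by CYP2C19
    phenotype, ontogeny-based pediatric extrapolation down to six months
    of age, virtual clinical trials, noncompartmental analysis, parameter
    estimation, synthetic-data generation, and Morris and Sobol global
    sensitivity analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
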