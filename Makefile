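# Reproduce the acceptance analysis against the installed package.
demo:
	Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json

test:
	Rscript -e 'testthat::test_dir("tests/testthat", package = "dualmlc", load_package = "installed")'

install:
	R CMD INSTALL .
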