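# Diagnostic-fragment registry, v1.
# kind = anion: mz is the electron-inclusive fragment m/z (Da).
# kind = neutral-loss: mz is empty; the neutral monoisotopic mass is
#   recomputed from the composition at load time.
# The SO3 neutral loss is stored at its computed monoisotopic mass
# (79.9568); a widely circulated rounded value of 79.9597 for this loss is
# inconsistent with the elemental masses and is not used.
name	composition	kind	mz	class_tag
glycine fragment	C2H4NO2	anion	74.0248	glycine-conjugate
taurine SO3 radical fragment	O3S	anion	79.9574	taurine-conjugate
taurine vinylsulfonate fragment	C2H3O3S	anion	106.9808	taurine-conjugate
taurine fragment	C2H6NO3S	anion	124.0074	taurine-conjugate
hydrogensulfate fragment	HO4S	anion	96.9601	sulfate
SO3 neutral loss	SO3	neutral-loss	NA	sulfate
glucuronide fragment	C6H9O7	anion	193.0354	glucuronide
demethylated phosphocholine fragment	C4H11NO4P	anion	168.0431	LPL-headgroup-PC
phosphoethanolamine fragment	C2H7NO4P	anion	140.0118	LPL-headgroup-PE
inositol cyclic phosphate fragment	C6H10O8P	anion	241.0119	LPL-headgroup-PI
glycerophosphate fragment	C3H6O5P	anion	152.9958	LPL-headgroup-PG
serine neutral loss	C3H5NO2	neutral-loss	NA	LPL-headgroup-PS
glycerophosphate fragment (PS)	C3H6O5P	anion	152.9958	LPL-headgroup-PS
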