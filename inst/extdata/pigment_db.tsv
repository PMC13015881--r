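name	ci_name	formula	adducts	observed_mz	note
Pigment Red 122 (2,9-dimethylquinacridone)	PR122	C22H16N2O2	[M+H]+		quinacridone magenta
Pigment Red 170	PR170	C26H22N4O4	[M+H]+		naphthol red
Pigment Red 5	PR5		observed	627.1674	printed reference m/z; formula assignment not established
Pigment Brown 23	PBr23		observed	887.0336	printed reference m/z; formula assignment not established
Pigment Blue 15 (copper phthalocyanine)	PB15	C32H16CuN8	M+.;[M+H]+		Cu isotope pattern diagnostic
Pigment Yellow 74	PY74	C18H18N4O6	[M+H]+		arylide yellow
Pigment Yellow 64	PY64		observed	387.1299	isobar of PY74 at printed precision
Pigment Yellow 101	PY101		observed	341.1284	isobar of PR122 at printed precision
Gold leaf	gilding	Au	M+.		gilding layer marker
Iron hydroxide hydrate cluster	ochre	FeO4H5	[M+H]+		FeO(OH).2H2O related cluster ion, yellow ochre
Ferric oxide species	ochre		observed	106.943	printed reference m/z; ionic formula not established
Lead oxide species	lead white		observed	262.935	printed reference m/z; ionic formula not established
Ursolic acid		C30H48O3	[M+Na]+		dammar/mastic varnish marker
Oleanolic acid		C30H48O3	[M+Na]+		isobar of ursolic acid
Moronic acid		C30H46O3	[M+H]+;[M+Na]+		varnish marker
Dammarenolic acid		C30H50O3	[M+Na]+		varnish marker
Asiatic acid		C30H48O5	[M+Na]+		varnish marker
Hydroxyoleanonic lactone		C30H46O4	[M+Na]+		varnish marker
Shoreic acid		C30H50O4	[M+Na]+		varnish marker, formula per common database entries
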