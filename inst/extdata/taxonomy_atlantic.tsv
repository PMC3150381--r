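species	genus	family	order	class	phylum
Salmo trutta	Salmo	Salmonidae	Salmoniformes	Actinopterygii	Chordata
Salmo salar	Salmo	Salmonidae	Salmoniformes	Actinopterygii	Chordata
Scomber scombrus	Scomber	Scombridae	Scombriformes	Actinopterygii	Chordata
Thunnus alalunga	Thunnus	Scombridae	Scombriformes	Actinopterygii	Chordata
Sardina pilchardus	Sardina	Clupeidae	Clupeiformes	Actinopterygii	Chordata
Engraulis encrasicolus	Engraulis	Engraulidae	Clupeiformes	Actinopterygii	Chordata
Micromesistius poutassou	Micromesistius	Gadidae	Gadiformes	Actinopterygii	Chordata
Merluccius merluccius	Merluccius	Merlucciidae	Gadiformes	Actinopterygii	Chordata
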