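region_id	area	cluster
r001	white matter	posterior_cortical
r002	cerebral cortex	posterior_cortical
r003	cerebral nuclei	posterior_cortical
r004	cerebellum	posterior_cortical
r005	other	posterior_cortical
r006	white matter	posterior_cortical
r007	cerebral cortex	posterior_cortical
r008	cerebral nuclei	posterior_cortical
r009	cerebellum	posterior_cortical
r010	other	posterior_cortical
r011	white matter	posterior_cortical
r012	cerebral cortex	posterior_cortical
r013	cerebral nuclei	posterior_cortical
r014	cerebellum	posterior_cortical
r015	other	posterior_cortical
r016	white matter	posterior_cortical
r017	cerebral cortex	posterior_cortical
r018	cerebral nuclei	posterior_cortical
r019	cerebellum	posterior_cortical
r020	other	hippocampal
r021	white matter	hippocampal
r022	cerebral cortex	hippocampal
r023	cerebral nuclei	hippocampal
r024	cerebellum	hippocampal
r025	other	hippocampal
r026	white matter	hippocampal
r027	cerebral cortex	hippocampal
r028	cerebral nuclei	hippocampal
r029	cerebellum	hippocampal
r030	other	hippocampal
r031	white matter	hippocampal
r032	cerebral cortex	hippocampal
r033	cerebral nuclei	anterior_cortical
r034	cerebellum	anterior_cortical
r035	other	anterior_cortical
r036	white matter	anterior_cortical
r037	cerebral cortex	anterior_cortical
r038	cerebral nuclei	anterior_cortical
r039	cerebellum	anterior_cortical
r040	other	anterior_cortical
r041	white matter	anterior_cortical
r042	cerebral cortex	anterior_cortical
r043	cerebral nuclei	anterior_cortical
r044	cerebellum	anterior_cortical
r045	other	anterior_cortical
r046	white matter	anterior_cortical
r047	cerebral cortex	anterior_cortical
r048	cerebral nuclei	anterior_cortical
r049	cerebellum	anterior_cortical
r050	other	anterior_cortical
r051	white matter	anterior_cortical
r052	cerebral cortex	anterior_cortical
r053	cerebral nuclei	anterior_cortical
r054	cerebellum	anterior_cortical
r055	other	anterior_cortical
r056	white matter	anterior_cortical
r057	cerebral cortex	subcortical
r058	cerebral nuclei	subcortical
r059	cerebellum	subcortical
r060	other	subcortical
r061	white matter	subcortical
r062	cerebral cortex	subcortical
r063	cerebral nuclei	subcortical
r064	cerebellum	subcortical
r065	other	subcortical
r066	white matter	subcortical
r067	cerebral cortex	subcortical
r068	cerebral nuclei	subcortical
r069	cerebellum	subcortical
r070	other	subcortical
r071	white matter	subcortical
r072	cerebral cortex	subcortical
r073	cerebral nuclei	subcortical
r074	cerebellum	subcortical
r075	other	subcortical
r076	white matter	subcortical
r077	cerebral cortex	subcortical
r078	cerebral nuclei	subcortical
r079	cerebellum	subcortical
r080	other	subcortical
r081	white matter	subcortical
r082	cerebral cortex	subcortical
r083	cerebral nuclei	subcortical
r084	cerebellum	subcortical
r085	other	subcortical
r086	white matter	subcortical
r087	cerebral cortex	subcortical
r088	cerebral nuclei	subcortical
r089	cerebellum	subcortical
r090	other	subcortical
r091	white matter	subcortical
r092	cerebral cortex	subcortical
r093	cerebral nuclei	subcortical
r094	cerebellum	subcortical
r095	other	subcortical
r096	white matter	subcortical
r097	cerebral cortex	midbrain
r098	cerebral nuclei	midbrain
r099	cerebellum	midbrain
r100	other	midbrain
r101	white matter	midbrain
r102	cerebral cortex	midbrain
r103	cerebral nuclei	midbrain
r104	cerebellum	midbrain
r105	other	midbrain
r106	white matter	brainstem_cerebellum
r107	cerebral cortex	brainstem_cerebellum
r108	cerebral nuclei	brainstem_cerebellum
r109	cerebellum	brainstem_cerebellum
r110	other	brainstem_cerebellum
r111	white matter	brainstem_cerebellum
r112	cerebral cortex	brainstem_cerebellum
r113	cerebral nuclei	brainstem_cerebellum
r114	cerebellum	brainstem_cerebellum
r115	other	brainstem_cerebellum
r116	white matter	brainstem_cerebellum
r117	cerebral cortex	brainstem_cerebellum
r118	cerebral nuclei	brainstem_cerebellum
r119	cerebellum	brainstem_cerebellum
r120	other	brainstem_cerebellum
r121	white matter	brainstem_cerebellum
r122	cerebral cortex	brainstem_cerebellum
r123	cerebral nuclei	brainstem_cerebellum
r124	cerebellum	brainstem_cerebellum
r125	other	brainstem_cerebellum
r126	white matter	brainstem_cerebellum
r127	cerebral cortex	brainstem_cerebellum
r128	cerebral nuclei	brainstem_cerebellum
r129	cerebellum	brainstem_cerebellum
r130	other	brainstem_cerebellum
r131	white matter	brainstem_cerebellum
r132	cerebral cortex	brainstem_cerebellum
r133	cerebral nuclei	brainstem_cerebellum
r134	cerebellum	brainstem_cerebellum
r135	other	brainstem_cerebellum
r136	white matter	brainstem_cerebellum
r137	cerebral cortex	brainstem_cerebellum
r138	cerebral nuclei	brainstem_cerebellum
r139	cerebellum	brainstem_cerebellum
r140	other	brainstem_cerebellum
r141	white matter	brainstem_cerebellum
r142	cerebral cortex	brainstem_cerebellum
r143	cerebral nuclei	brainstem_cerebellum
r144	cerebellum	brainstem_cerebellum
r145	other	brainstem_cerebellum
r146	white matter	brainstem_cerebellum
r147	cerebral cortex	brainstem_cerebellum
r148	cerebral nuclei	brainstem_cerebellum
r149	cerebellum	brainstem_cerebellum
r150	other	brainstem_cerebellum
r151	white matter	brainstem_cerebellum
r152	cerebral cortex	brainstem_cerebellum
r153	cerebral nuclei	brainstem_cerebellum
r154	cerebellum	brainstem_cerebellum
r155	other	brainstem_cerebellum
r156	white matter	brainstem_cerebellum
r157	cerebral cortex	
r158	cerebral nuclei	
r159	cerebellum	
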