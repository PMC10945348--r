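Exhaustion.synthetic	synthetic placeholder set over the generator gene universe	G0101	G0102	G0103	G0104	G0105	G0106	G0107	G0108	G0109	G0110	G0111	G0112	G0113	G0114	G0115
Activation.synthetic	synthetic placeholder set over the generator gene universe	G0201	G0202	G0203	G0204	G0205	G0206	G0207	G0208	G0209	G0210	G0211	G0212	G0213	G0214	G0215
AntigenPresentation.synthetic	synthetic placeholder set over the generator gene universe	G0301	G0302	G0303	G0304	G0305	G0306	G0307	G0308	G0309	G0310	G0311	G0312	G0313	G0314	G0315
Immunochemotaxis.synthetic	synthetic placeholder set over the generator gene universe	G0401	G0402	G0403	G0404	G0405	G0406	G0407	G0408	G0409	G0410	G0411	G0412	G0413	G0414	G0415
ECM.synthetic	synthetic placeholder set over the generator gene universe	G0501	G0502	G0503	G0504	G0505	G0506	G0507	G0508	G0509	G0510	G0511	G0512	G0513	G0514	G0515
Glycolysis.synthetic	synthetic placeholder set over the generator gene universe	G0601	G0602	G0603	G0604	G0605	G0606	G0607	G0608	G0609	G0610	G0611	G0612	G0613	G0614	G0615
Immunosuppression.synthetic	synthetic placeholder set over the generator gene universe	G0701	G0702	G0703	G0704	G0705	G0706	G0707	G0708	G0709	G0710	G0711	G0712	G0713	G0714	G0715
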