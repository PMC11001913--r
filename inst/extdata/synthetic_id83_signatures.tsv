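channel	ID1	ID2	ID6	ID8
1:Del:C:0	0.0016358334056886632	0.005565589454063916	0.02145267477739009	0.03399058314951483
1:Del:C:1	0.01349249903091892	0.06395952113155812	1.5155859916637214e-7	3.850975568469548e-4
1:Del:C:2	1.6794529008648145e-5	0.0015100424121709142	0.005658368883403893	9.840560161265328e-6
1:Del:C:3	0.02196982660282973	0.003246245910909151	0.0038356791315908487	1.394983278731721e-6
1:Del:C:4	7.752291514396661e-5	0.0015957012798736014	0.00898355297764271	0.07653750109413536
1:Del:C:5	9.526605771028841e-4	0.0065762760195431326	1.3571853425494153e-4	0.0048832726790986195
1:Del:T:0	0.015586174122512985	0.019709511027902304	3.5909184923699937e-6	9.493204074966869e-8
1:Del:T:1	0.03416686061210223	6.512617121179213e-4	0.0031869923785304245	2.1730782897893338e-4
1:Del:T:2	0.010348399407944318	2.675381031844375e-5	5.3924771965112245e-6	0.04914126242987489
1:Del:T:3	0.057353823776479636	0.0011295204861242877	0.01580813112998982	0.007351192651632288
1:Del:T:4	0.0020610268910048815	0.11318016721710639	0.004767483923923424	2.539549550092651e-6
1:Del:T:5	4.981806050629966e-4	0.021355885011075357	0.006671230306701931	4.379487978676338e-4
1:Ins:C:0	0.00800877541130514	0.016948357879702065	7.638045510074565e-5	0.048087011991333126
1:Ins:C:1	4.4829910360589284e-4	0.003276620682091847	0.01243887786611836	0.0020233169123317755
1:Ins:C:2	0.005042340975602547	5.358244753632142e-4	0.0019501853527927621	2.183273775431911e-5
1:Ins:C:3	0.18018139073743827	0.0014778984304123907	0.03139582350297619	0.04183296776555062
1:Ins:C:4	0.0062407254274069	0.00482925702004014	9.839803578922347e-6	6.806661934183289e-4
1:Ins:C:5	6.791241813566912e-6	3.7432135442078735e-7	0.026511136613026134	3.614503032172267e-5
1:Ins:T:0	1.4113961398214814e-4	0.005984503997245021	1.3053232805677181e-4	0.03016855438827737
1:Ins:T:1	0.0019149652508404114	0.008918988296518982	0.022374983790756014	0.021891178608559804
1:Ins:T:2	0.026581318965205502	0.01163377732377635	0.00889899808317355	0.008715959718284124
1:Ins:T:3	0.011076158017232903	7.896495324764e-5	4.5406924901236615e-4	2.0354185831793522e-6
1:Ins:T:4	2.1186850496287716e-4	4.6387180892551325e-4	2.4319813799931014e-4	5.86699139049881e-4
1:Ins:T:5	0.04677430725507274	0.16588176609733515	5.162173641003283e-4	0.005348115839609337
2:Del:R:0	0.02580440399477059	1.7128032913935317e-4	5.003134453054123e-4	2.571951606633674e-4
2:Del:R:1	0.01677805857083374	2.0007112351903914e-5	5.921447935686064e-4	0.002174873550260797
2:Del:R:2	9.337231794502434e-5	0.016492414228242994	2.711021628931942e-4	4.4183987284230595e-6
2:Del:R:3	1.6069626934706266e-4	0.06457008556718992	1.7016575516588385e-4	0.018777901297911063
2:Del:R:4	3.2145011848849927e-6	0.09265918252417482	0.00892176056953742	7.903201531027309e-4
2:Del:R:5	2.8386100538630158e-6	1.1759200342954274e-7	0.042869934684003616	0.05039013756463151
3:Del:R:0	0.010462156431352508	0.004156271553143523	1.426939203658165e-9	0.002074677345791311
3:Del:R:1	0.009035140957150795	0.0028318432940654566	0.01091971764237071	0.037407762402956575
3:Del:R:2	0.010507672347964282	2.6531198662382982e-5	0.01376018919739111	1.6602618033974832e-6
3:Del:R:3	0.00703205841775295	1.497388390960536e-6	0.0024742879905220306	0.04227718674472652
3:Del:R:4	8.349058340977588e-4	1.6286278352952696e-4	5.176385989042403e-4	5.984959509011789e-4
3:Del:R:5	9.798805674590709e-4	0.007480657382670212	0.0023246808594236715	3.4987159375168007e-7
4:Del:R:0	0.009498150055747738	4.2048118303137656e-7	6.343220978599092e-5	0.0010816671921994967
4:Del:R:1	1.8822656971767673e-4	0.0014094502848132984	0.0110591631881523	0.016193316998713583
4:Del:R:2	2.1263303977066836e-4	1.7628220026190486e-6	0.03209040491896067	6.594371234402807e-8
4:Del:R:3	4.831674377062362e-10	0.00774174915488693	2.066004615992952e-4	0.0012150838968087714
4:Del:R:4	0.0044367428941500435	1.0933328008006893e-5	9.262395937036235e-4	0.01630668139778248
4:Del:R:5	0.031701869020890686	0.0030643593935538024	0.010708781490872869	6.883889150387526e-4
5:Del:R:0	0.03603282738580313	4.4555014909243215e-5	0.00381649398429097	0.009830798602996849
5:Del:R:1	0.015598597724923544	4.317494315387798e-4	1.7973351817328565e-6	2.9948500898653757e-5
5:Del:R:2	0.01995673480144181	0.0021359336864267314	0.0030474440595847376	1.7976998709389553e-4
5:Del:R:3	0.013838156686512525	0.012975871285089034	1.5221181855927004e-5	1.3434391073650277e-4
5:Del:R:4	0.08514673295639762	0.012015419879535071	0.003572193224170754	0.004970203866216952
5:Del:R:5	0.010001237108931442	0.003931693004610706	0.013905407920107936	0.016010697990965914
2:Ins:R:0	0.020929503980503777	0.007674316015478578	0.03302756796866769	5.626843170654922e-6
2:Ins:R:1	2.0159971810548513e-4	9.273405198529033e-9	0.024477909134745342	0.005254331151175111
2:Ins:R:2	0.006532508353400752	0.0015861551457483744	0.15060372371148392	1.3006969910217703e-5
2:Ins:R:3	0.0020902377260172875	0.00311949118504456	0.11984925334039212	2.144379935782825e-6
2:Ins:R:4	0.004428960094625799	0.02628469573059991	0.011854158880565192	0.1128625882650104
2:Ins:R:5	9.523137055690811e-4	4.187470900666768e-5	0.010878626229515076	9.204195744153195e-4
3:Ins:R:0	5.23680069597997e-4	0.0027433391474139942	4.4636631364101096e-4	1.1672494223778052e-4
3:Ins:R:1	0.005753539423446763	0.007569128845297733	8.5984203788417e-7	9.488448058715287e-4
3:Ins:R:2	0.004985577063415192	0.0015591609557604744	0.0030835615223302497	0.03569295430601936
3:Ins:R:3	1.4960908377462239e-7	6.187683279375343e-4	2.6854072468413676e-4	8.818012808541406e-4
3:Ins:R:4	1.1941799759748462e-5	0.010010339488134533	0.08942809027483938	3.344407894412848e-4
3:Ins:R:5	3.053880079127775e-6	0.028405210330817717	1.5770393913148238e-5	0.00467728674252538
4:Ins:R:0	0.018250849531968587	0.04325390499821448	2.7223826993205446e-5	3.3168168878581843e-4
4:Ins:R:1	0.002596733648382702	0.0011459897006617628	2.3310359349927787e-4	0.012385524945410578
4:Ins:R:2	7.781592143064131e-5	5.170841062029737e-4	0.026246557577514974	0.018215443049945587
4:Ins:R:3	2.9481701343653425e-5	0.010874060047653556	0.0010563490988813578	2.6532582489644814e-4
4:Ins:R:4	0.006190008925599721	0.0039909462509002906	0.04238416400964026	5.913084287202496e-5
4:Ins:R:5	0.056056153065889174	0.0029275858847823575	0.0042286751795721335	2.2253568944544954e-4
5:Ins:R:0	1.7450326277469737e-6	0.006282061555910056	3.0841952732796e-5	0.002653848632168418
5:Ins:R:1	0.007844833474270377	8.077118690302924e-4	0.026805475671580502	0.0325903666378084
5:Ins:R:2	2.3762594713015739e-4	0.005032678126626624	0.003987611759521332	2.0500938957909032e-4
5:Ins:R:3	1.5474661337056462e-5	2.484136186115854e-4	0.002256528938884678	2.1487537790448335e-4
5:Ins:R:4	0.020178574050643404	0.0485892018575663	0.032205610325793416	0.013311950853734053
5:Ins:R:5	0.004399732497863845	0.010391771030487504	0.0036459992182860095	0.02046933877457574
2:Del:M:1	0.0015691291900878392	0.006239149981163464	6.812240901657139e-6	0.0828349506748062
3:Del:M:1	5.453838815488583e-4	0.005150206154405233	0.0011300149366034304	8.165895501669939e-4
3:Del:M:2	0.030541714888831548	0.0017229589959795132	2.278803940707737e-8	2.3021085147898156e-6
4:Del:M:1	0.009287708157336953	6.757585155838326e-4	0.025233028125104626	4.022449500451863e-5
4:Del:M:2	0.028958951062377523	2.102903236378775e-6	0.0032411097685379124	5.640022367383048e-4
4:Del:M:3	8.385753336559661e-5	0.03528125679511327	1.1770576699482963e-4	6.518466472525648e-4
5:Del:M:1	0.002873399456480334	9.77487475905996e-4	1.5385468060298443e-4	6.378878375031208e-4
5:Del:M:2	0.006579480132182752	0.014852907161849149	0.006088355535925608	0.06428416631240981
5:Del:M:3	0.0026851463032038923	0.009010255014683674	0.008863865117409438	7.090715592240462e-5
5:Del:M:4	2.6311779786665365e-4	0.0031307577817995384	5.722969785719143e-4	0.032587856914325405
5:Del:M:5	0.0012260271869905868	0.008409931540088894	0.029306038332893546	0.001125598447374107
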