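channel	RS1	RS2	RS3	RS4	RS5	RS6
clustered:del:1-10Kb	0.003225684265206109	0.03353501333677864	0.013021856213506272	0.008060656478876112	0.04871059178945409	0.1628480633328052
clustered:del:10-100Kb	0.026605729942299015	0.02244266522737918	0.11792473546968038	0.001318155944166081	0.04510511857523474	0.0045117990922991
clustered:del:100Kb-1Mb	3.3116971310374626e-5	0.0026645842536998196	3.6710066559712632e-6	0.003635706636210064	0.014759324347577346	0.06855671781239109
clustered:del:1Mb-10Mb	0.043322091195600765	0.0031272680390111714	0.01650309308898976	0.011880222236128014	0.028808892018127155	0.04158872762942972
clustered:del:>10Mb	1.528666957791633e-4	0.030313144362170204	4.998911880934577e-4	9.208499070961501e-7	3.481177064717236e-8	0.014450671201735094
clustered:tds:1-10Kb	0.0018785422910160352	6.007211032842382e-4	3.2553881150394415e-5	0.014722189596708676	0.005954325079355238	0.03881780833427238
clustered:tds:10-100Kb	0.03073422785408105	6.786138345787508e-4	0.04244945250310917	0.021941172864555804	0.011710370607646122	0.08129420560720502
clustered:tds:100Kb-1Mb	0.06737330603757356	1.542018625134891e-9	0.009255670654711204	0.028619694391610752	0.0986710684711045	5.74326327603516e-7
clustered:tds:1Mb-10Mb	0.020405909932021106	0.014159770803664705	0.0033009604573001057	1.9425787228852533e-4	1.5719498227991017e-4	0.02144220281070281
clustered:tds:>10Mb	0.11309545719132061	0.10117584229987381	0.0011473182950225062	0.0011411486603924847	0.010298319890339079	0.014535179934553015
clustered:inv:1-10Kb	0.004064119236935563	0.11499800402311308	0.06425028212018867	0.40807773079374576	0.028414026101565945	0.034042878588613656
clustered:inv:10-100Kb	9.823575758963388e-4	0.04978259365326512	0.019538453277130528	4.213584753117479e-4	0.005852990614771071	5.143009225151734e-4
clustered:inv:100Kb-1Mb	0.015792427723983857	0.06369149565789073	0.060920638622780236	4.921853197240364e-5	0.0023228167706197686	1.360766754107087e-5
clustered:inv:1Mb-10Mb	8.839967197018794e-4	0.044164183433882565	1.7641020473977857e-4	0.04057219266415808	0.037578174888394655	0.012077002815607292
clustered:inv:>10Mb	0.00994294399921355	0.2717439915062747	0.006044740002152552	0.15884575270289553	0.10663134480287441	2.043461500695348e-5
clustered:trans	0.3552979630832443	0.03191873601742815	0.01384118266559756	0.22794638513482895	0.16237239591679542	0.05990439307370117
non-clustered:del:1-10Kb	0.012306026851299934	0.06679606785172873	0.005648713837542867	2.8928241510800425e-7	0.004301972120207479	0.018066223553109148
non-clustered:del:10-100Kb	1.3391584853966409e-5	6.434012225997932e-4	5.53518124483482e-4	0.01022464315320943	0.001941100698726217	0.025280407866791133
non-clustered:del:100Kb-1Mb	2.783118564740499e-4	0.020848361796925795	0.00257918040744896	0.006966481082240432	0.04082052668663086	2.894412228668169e-4
non-clustered:del:1Mb-10Mb	0.0037761016840537763	0.006670949349939311	0.013558205199304686	6.526812198894982e-5	0.014981757248520857	0.047136718626662556
non-clustered:del:>10Mb	0.0524154489303827	0.014134932164125895	0.15581032685005702	3.683652947976964e-6	0.010989970371089628	0.007390163263426031
non-clustered:tds:1-10Kb	0.02184097018124141	0.003039288984229068	0.003678579789768151	4.006508774115956e-4	0.023582457726580162	0.1189734407267687
non-clustered:tds:10-100Kb	4.177814809105116e-4	0.0016713138301820308	0.007908105430840242	0.018402804367143658	0.003032098752477847	3.7287612084740806e-5
non-clustered:tds:100Kb-1Mb	0.09223380963117456	0.01836229898587858	0.0038872513985956946	1.0344054747538065e-6	0.01889235215484352	0.10046308038806931
non-clustered:tds:1Mb-10Mb	0.05088345772221933	0.015911363409190925	0.01602031562984352	0.003467320655096699	9.325288533830463e-4	4.946479646733044e-4
non-clustered:tds:>10Mb	0.03308449341139407	4.774742163193925e-7	0.04801388911270372	4.336633371747206e-6	0.18240075946029674	0.08478926528363151
non-clustered:inv:1-10Kb	1.8411998174978607e-4	3.8112000540813397e-5	0.001586523764324329	0.01904510364114944	0.03901004452912761	0.03372246059657305
non-clustered:inv:10-100Kb	3.168754383591539e-4	9.746393472414798e-6	6.517434553061982e-5	2.6896552818910655e-5	0.023421370416556838	0.0017206804872660865
non-clustered:inv:100Kb-1Mb	6.338644177647616e-6	0.05824719901745715	0.0027515990272170016	0.007538482722231058	0.019333544862382326	9.215913464852613e-4
non-clustered:inv:1Mb-10Mb	5.597428047354891e-6	0.008287420338858075	0.27571561723810956	1.0960764288569731e-4	0.0064678779928688136	0.001956188725678662
non-clustered:inv:>10Mb	0.020630226319734195	2.4834786207392944e-4	0.05202458312506169	0.0010621259493370282	0.002536754294000818	0.001895921348398658
non-clustered:trans	0.01781630813874421	9.409022426759278e-5	0.041287507068359874	0.005254507426521445	7.894164397089697e-6	0.0022439132228087907
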