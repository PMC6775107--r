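# Synthetic chlorophyll-a absorption reference (methanol-like), visible band
# Analytic stand-in shape: Gaussian Qy band at 660 nm (sd 11.9 nm), vibronic
# satellite at 615 nm (rel. amp 0.20, sd 12.7 nm), Soret-band tail
# (430 nm, rel. amp 1.10, sd 34 nm); max-normalized over 520-720 nm.
# extinction_convention: decadic
# epsilon_peak_M_cm: 71430
# molar_mass_g_mol: 893.5
# source: synthetic analytic stand-in generated by the isoct package
wavelength_nm	relative_absorption
520	0.03309
521	0.0305982
522	0.0282697
523	0.0260958
524	0.0240682
525	0.0221789
526	0.0204203
527	0.0187849
528	0.0172655
529	0.0158553
530	0.0145477
531	0.0133363
532	0.0122153
533	0.0111788
534	0.0102215
535	0.00933799
536	0.00852351
537	0.00777334
538	0.00708307
539	0.00644851
540	0.00586573
541	0.005331
542	0.00484083
543	0.00439194
544	0.00398123
545	0.00360582
546	0.00326299
547	0.00295023
548	0.00266517
549	0.00240561
550	0.00216952
551	0.001955
552	0.00176031
553	0.00158383
554	0.00142411
555	0.00127979
556	0.00114969
557	0.00103275
558	0.000928048
559	0.000834846
560	0.000752566
561	0.000680835
562	0.000619507
563	0.000568708
564	0.000528883
565	0.000500858
566	0.000485918
567	0.000485896
568	0.000503282
569	0.000541349
570	0.000604292
571	0.000697399
572	0.00082722
573	0.00100176
574	0.00123071
575	0.00152559
576	0.00190004
577	0.00236995
578	0.00295367
579	0.00367213
580	0.00454891
581	0.00561029
582	0.00688512
583	0.0084047
584	0.0102024
585	0.0123133
586	0.0147735
587	0.0176194
588	0.0208867
589	0.0246096
590	0.0288189
591	0.0335415
592	0.0387982
593	0.0446027
594	0.0509597
595	0.0578638
596	0.0652979
597	0.0732324
598	0.081624
599	0.0904154
600	0.0995353
601	0.108898
602	0.118407
603	0.12795
604	0.13741
605	0.146659
606	0.155566
607	0.163997
608	0.171823
609	0.178917
610	0.185163
611	0.190459
612	0.194718
613	0.197871
614	0.199876
615	0.20071
616	0.200381
617	0.198922
618	0.196396
619	0.192894
620	0.188535
621	0.183464
622	0.177854
623	0.171901
624	0.165823
625	0.159859
626	0.154266
627	0.149314
628	0.145288
629	0.142481
630	0.141192
631	0.141722
632	0.144371
633	0.149429
634	0.157176
635	0.16787
636	0.181744
637	0.198996
638	0.219779
639	0.244195
640	0.272286
641	0.30402
642	0.339291
643	0.377906
644	0.419583
645	0.463946
646	0.510529
647	0.558775
648	0.608043
649	0.657622
650	0.706739
651	0.754581
652	0.80031
653	0.843087
654	0.882098
655	0.916571
656	0.945809
657	0.969202
658	0.986254
659	0.996596
660	1
661	0.996384
662	0.985818
663	0.968517
664	0.944835
665	0.915255
666	0.880369
667	0.840859
668	0.797473
669	0.751007
670	0.702272
671	0.652081
672	0.601217
673	0.55042
674	0.500369
675	0.451669
676	0.404841
677	0.360314
678	0.318428
679	0.279431
680	0.243484
681	0.210669
682	0.180994
683	0.154404
684	0.130794
685	0.110015
686	0.0918855
687	0.0762036
688	0.0627535
689	0.0513137
690	0.041664
691	0.033591
692	0.0268917
693	0.0213769
694	0.0168735
695	0.0132251
696	0.0102927
697	0.00795405
698	0.00610355
699	0.0046506
700	0.00351859
701	0.0026434
702	0.00197192
703	0.00146066
704	0.00107434
705	0.000784633
706	0.000569018
707	0.000409749
708	0.000292984
709	0.000208018
710	0.000146654
711	0.000102664
712	7.13635e-05
713	4.92569e-05
714	3.37592e-05
715	2.29747e-05
716	1.55253e-05
717	1.04175e-05
718	6.94098e-06
719	4.59209e-06
720	3.01671e-06
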